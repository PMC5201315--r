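#' Reference reaction-time level means by gender and age group
#'
#' Mean choice reaction time (seconds) at each of the three mental-state
#' levels, for male/female drivers and for the two age bands used in the
#' growth-rate analysis.  These seed the synthetic generator's per-profile
#' reaction-time means.
#'
#' @return A list with elements `gender` and `age`, each a named list of
#'   length-3 numeric vectors (levels 1, 2, 3).
#' @export
reference_rt_means <- function() {
  list(
    gender = list(
      male   = c(1.21, 1.30, 1.40),
      female = c(1.24, 1.35, 1.46)
    ),
    age = list(
      `20-30`  = c(1.21, 1.31, 1.41),
      `over30` = c(1.25, 1.33, 1.45)
    )
  )
}

#' Simulation configuration for a synthetic driving session
#'
#' Describes one simulator-driving session: a 3-level mental-state
#' trajectory over three periods (alert start, long stable middle, fatigued
#' end), choice reaction times sampled every few minutes, EEG synthesized as
#' a sum of band-limited noise components whose alpha/beta band-power ratio
#' rises with fatigue level, and an RR-interval series whose dispersion
#' (RRSD) co-varies with level.
#'
#' @param duration_min Session length in minutes.
#' @param rt_interval_min Minutes between reaction-time samples.
#' @param eeg_fs EEG sampling rate in Hz.
#' @param period_bounds Two minute marks splitting the session into three
#'   periods: alert (unstable behaviour), stable, fatigued.
#' @param gender `"male"` or `"female"`.
#' @param age_group `"20-30"` or `"over30"`.
#' @param level_rt_means_s Length-3 mean reaction time (s) per level.
#'   Default: the gender row of [reference_rt_means()], shifted up by the
#'   mean age-band gap (+0.033 s) for the `over30` group.
#' @param alpha_beta_by_level Target alpha/beta band-power ratio per level;
#'   must be strictly increasing (the ratio rises as fatigue accumulates).
#' @param beta_power_by_level Beta-band variance per level (beta activity
#'   declines with drowsiness).
#' @param rrsd_by_level Target RR-interval standard deviation (s) per level.
#' @param rr_mean_s Mean RR interval in seconds (0.8 s = 75 bpm).
#' @param rt_noise_sd SD (s) of Gaussian reaction-time noise.
#' @param rt_period1_factor Multiplier on `rt_noise_sd` during period 1
#'   (reaction times fluctuate strongly while the driver adapts).
#' @param band_jitter_sd SD of multiplicative log-normal jitter applied to
#'   each band variance per 60-s epoch.
#' @param ratio_jitter_sd SD of log-normal jitter on the per-epoch
#'   alpha/beta target ratio (kept small: the ratio tracks level tightly).
#' @param level2_flip_prob Probability that a 3-min block in period 2 drops
#'   back to level 1 (level transitions are not strictly ordered).
#' @param rng_seed Integer seed; the session is a deterministic function of
#'   the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_min = 240,
                       rt_interval_min = 3,
                       eeg_fs = 256,
                       period_bounds = c(44, 188),
                       gender = c("male", "female"),
                       age_group = c("20-30", "over30"),
                       level_rt_means_s = NULL,
                       alpha_beta_by_level = c(0.7, 1.1, 1.8),
                       beta_power_by_level = c(1.0, 0.85, 0.7),
                       rrsd_by_level = c(0.040, 0.055, 0.070),
                       rr_mean_s = 0.8,
                       rt_noise_sd = 0.08,
                       rt_period1_factor = 2,
                       band_jitter_sd = 0.15,
                       ratio_jitter_sd = 0.05,
                       level2_flip_prob = 0.2,
                       rng_seed = 1L) {
  gender <- match.arg(gender)
  age_group <- match.arg(age_group)
  if (is.null(level_rt_means_s)) {
    ref <- reference_rt_means()
    age_offset <- if (age_group == "over30") {
      mean(ref$age$over30 - ref$age$`20-30`)
    } else 0
    level_rt_means_s <- ref$gender[[gender]] + age_offset
  }
  stopifnot(
    duration_min > 0,
    rt_interval_min > 0,
    eeg_fs > 0,
    length(period_bounds) == 2, diff(period_bounds) > 0,
    length(level_rt_means_s) == 3, all(level_rt_means_s > 0),
    length(alpha_beta_by_level) == 3, all(diff(alpha_beta_by_level) > 0),
    all(alpha_beta_by_level > 0),
    length(beta_power_by_level) == 3, all(beta_power_by_level > 0),
    length(rrsd_by_level) == 3, all(rrsd_by_level > 0),
    rr_mean_s > 0, rt_noise_sd >= 0, band_jitter_sd >= 0,
    ratio_jitter_sd >= 0, level2_flip_prob >= 0, level2_flip_prob <= 1
  )
  structure(list(
    duration_min = duration_min, rt_interval_min = rt_interval_min,
    eeg_fs = eeg_fs, period_bounds = period_bounds,
    gender = gender, age_group = age_group,
    level_rt_means_s = level_rt_means_s,
    alpha_beta_by_level = alpha_beta_by_level,
    beta_power_by_level = beta_power_by_level,
    rrsd_by_level = rrsd_by_level, rr_mean_s = rr_mean_s,
    rt_noise_sd = rt_noise_sd, rt_period1_factor = rt_period1_factor,
    band_jitter_sd = band_jitter_sd, ratio_jitter_sd = ratio_jitter_sd,
    level2_flip_prob = level2_flip_prob,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# Band-limited Gaussian noise: white noise brick-wall filtered in the
# frequency domain, then rescaled to unit sample SD.  Exact variance
# control is what lets the generator hit the target alpha/beta ratios.
band_limited_noise <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)               # two-sided frequency axis
  X[f < lo | f > hi] <- 0 + 0i
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) stop("degenerate band: no frequency bins in [lo, hi]")
  y / s
}

# Piecewise-constant level per 3-min block; period 2 blocks may flip back
# to level 1 (transitions between adjacent levels are not strictly ordered).
level_trajectory <- function(cfg, block_starts_min) {
  p <- cfg$period_bounds
  lev <- ifelse(block_starts_min <= p[1], 1L,
                ifelse(block_starts_min <= p[2], 2L, 3L))
  in2 <- lev == 2L
  flips <- runif(sum(in2)) < cfg$level2_flip_prob
  lev[in2][flips] <- 1L
  lev
}

#' Simulate one synthetic driving session
#'
#' Generates a multichannel session record: EEG as a sum of delta
#' (1--4 Hz), theta (4--8 Hz), alpha (8--13 Hz) and beta (13--30 Hz)
#' band-limited noise components whose variances are set per 60-s epoch so
#' that the realized alpha/beta band-power ratio tracks the configured
#' per-level targets; an RR-interval series with level-dependent dispersion;
#' and reaction-time samples equal to the profile's level mean plus
#' truncated Gaussian noise (extra variance in the adaptation period).
#'
#' @param cfg A [sim_config()].
#' @return An object of class `fatigue_session`: list with `eeg` (numeric),
#'   `fs`, `rr_s` (positive RR intervals, s), `rt` (data.frame `time_min`,
#'   `rt_s`, `level`), `profile`, `epoch_level` (level per 60-s epoch) and
#'   the generating `cfg`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$duration_min * 60 < 60)
    stop("session shorter than one 60-s epoch")
  set.seed(cfg$rng_seed)

  block_min <- cfg$rt_interval_min
  n_blocks <- ceiling(cfg$duration_min / block_min)
  block_starts <- (seq_len(n_blocks) - 1) * block_min
  block_level <- level_trajectory(cfg, block_starts + block_min / 2)
  level_at <- function(t_min) {
    idx <- pmin(pmax(floor(t_min / block_min) + 1, 1), n_blocks)
    block_level[idx]
  }

  # --- EEG, built epoch by epoch (60 s) ------------------------------------
  epoch_s <- 60
  n_epochs <- floor(cfg$duration_min * 60 / epoch_s)
  n_ep_samp <- epoch_s * cfg$eeg_fs
  epoch_level <- level_at((seq_len(n_epochs) - 1) + 0.5) # epochs are 1 min
  eeg <- vector("list", n_epochs)
  jit <- function() exp(rnorm(1, 0, cfg$band_jitter_sd))
  for (e in seq_len(n_epochs)) {
    L <- epoch_level[e]
    v_delta <- 2.0 * jit()
    v_theta <- 1.0 * jit()
    v_beta  <- cfg$beta_power_by_level[L] * jit()
    ratio   <- cfg$alpha_beta_by_level[L] *
      exp(rnorm(1, 0, cfg$ratio_jitter_sd))
    v_alpha <- ratio * v_beta
    eeg[[e]] <-
      sqrt(v_delta) * band_limited_noise(n_ep_samp, cfg$eeg_fs, 1, 4) +
      sqrt(v_theta) * band_limited_noise(n_ep_samp, cfg$eeg_fs, 4, 8) +
      sqrt(v_alpha) * band_limited_noise(n_ep_samp, cfg$eeg_fs, 8, 13) +
      sqrt(v_beta)  * band_limited_noise(n_ep_samp, cfg$eeg_fs, 13, 30)
  }
  eeg <- unlist(eeg)

  # --- reaction times ------------------------------------------------------
  rt_times <- seq(cfg$rt_interval_min, cfg$duration_min,
                  by = cfg$rt_interval_min)
  rt_level <- level_at(rt_times - block_min / 2)
  noise_sd <- ifelse(rt_times <= cfg$period_bounds[1],
                     cfg$rt_noise_sd * cfg$rt_period1_factor,
                     cfg$rt_noise_sd)
  rt_s <- cfg$level_rt_means_s[rt_level] + rnorm(length(rt_times), 0, noise_sd)
  rt_s <- pmax(rt_s, 0.2)            # physiological floor

  # --- RR intervals, per 3-min block ---------------------------------------
  rr <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    n_rr <- ceiling(block_min * 60 / cfg$rr_mean_s)
    rr[[b]] <- pmax(rnorm(n_rr, cfg$rr_mean_s,
                          cfg$rrsd_by_level[block_level[b]]), 0.3)
  }
  rr <- unlist(rr)

  structure(list(
    eeg = eeg, fs = cfg$eeg_fs, rr_s = rr,
    rt = data.frame(time_min = rt_times, rt_s = rt_s, level = rt_level),
    profile = list(gender = cfg$gender, age_group = cfg$age_group),
    epoch_level = epoch_level,
    cfg = cfg
  ), class = "fatigue_session")
}

#' Simulate a cohort of synthetic driving sessions
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param profile_mix Named numeric vector of gender fractions summing to 1,
#'   e.g. `c(male = 0.6, female = 0.4)`; subject counts are the rounded
#'   fractions.  Age groups alternate within gender.
#' @param seed Master seed; each subject gets an independent derived seed.
#' @param cfg_fn Function `(gender, age_group, rng_seed) -> sim_config`,
#'   allowing cohort-wide overrides of the session configuration.
#' @return List of `fatigue_session`, one per subject.
#' @export
simulate_cohort <- function(n_subjects,
                            profile_mix = c(male = 0.6, female = 0.4),
                            seed = 1L,
                            cfg_fn = NULL) {
  stopifnot(n_subjects >= 1)
  if (is.null(names(profile_mix)) ||
      !setequal(names(profile_mix), c("male", "female")) ||
      any(profile_mix < 0) || abs(sum(profile_mix) - 1) > 1e-8)
    stop("profile_mix must be fractions over {male, female} summing to 1")
  n_male <- round(n_subjects * profile_mix[["male"]])
  genders <- c(rep("male", n_male), rep("female", n_subjects - n_male))
  ages <- rep(c("20-30", "over30"), length.out = n_subjects)
  if (is.null(cfg_fn))
    cfg_fn <- function(gender, age_group, rng_seed)
      sim_config(gender = gender, age_group = age_group, rng_seed = rng_seed)
  lapply(seq_len(n_subjects), function(i) {
    s <- simulate_session(cfg_fn(genders[i], ages[i],
                                 derive_seed(seed, paste0("subject", i))))
    s$subject_id <- i
    s
  })
}

#' Simulate a level-separated feature table directly
#'
#' Draws per-row (reaction time, alpha/beta) pairs from level-specific
#' Gaussians, bypassing signal synthesis.  Used to exercise the classifier
#' on a table whose class-conditional distributions are controlled exactly.
#'
#' @param n_by_level Integer length-3 row counts for levels 1, 2, 3.
#' @param rt_means,ab_means Length-3 per-level means of reaction time (s)
#'   and alpha/beta ratio.
#' @param rt_sd,ab_sd Within-level standard deviations.
#' @param seed Integer seed.
#' @return A data.frame with columns `reaction_time_s`, `alpha_over_beta`,
#'   `level`.
#' @export
simulate_feature_rows <- function(n_by_level = c(112, 72, 58),
                                  rt_means = c(1.21, 1.30, 1.40),
                                  ab_means = c(0.7, 1.1, 1.8),
                                  rt_sd = 0.04, ab_sd = 0.12,
                                  seed = 1L) {
  stopifnot(length(n_by_level) == 3, all(n_by_level >= 1))
  set.seed(seed)
  lev <- rep(1:3, times = n_by_level)
  out <- data.frame(
    reaction_time_s = pmax(rnorm(length(lev), rt_means[lev], rt_sd), 0.2),
    alpha_over_beta = pmax(rnorm(length(lev), ab_means[lev], ab_sd), 0.05),
    level = lev
  )
  out[sample(nrow(out)), , drop = FALSE]
}

#' Write / read a session directory
#'
#' A session is persisted as one directory holding `eeg.csv` (`t_s`,
#' `value`), `rr.csv` (`rr_s`), `rt.csv` (`t_min`, `rt_s`, `level`) and
#' `meta.json` (profile, sampling rate, seed).
#'
#' @param session A `fatigue_session`.
#' @param dir Directory path (created if missing).
#' @return `write_session` returns `dir` invisibly; `read_session` returns a
#'   `fatigue_session` (without the generating `cfg`).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "fatigue_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eeg <- data.frame(t_s = (seq_along(session$eeg) - 1) / session$fs,
                    value = session$eeg)
  write.csv(eeg, file.path(dir, "eeg.csv"), row.names = FALSE)
  write.csv(data.frame(rr_s = session$rr_s), file.path(dir, "rr.csv"),
            row.names = FALSE)
  rt <- session$rt
  names(rt) <- c("t_min", "rt_s", "level")
  write.csv(rt, file.path(dir, "rt.csv"), row.names = FALSE)
  meta <- list(profile = session$profile, fs = session$fs,
               seed = if (!is.null(session$cfg)) session$cfg$rng_seed else NA)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  eeg <- read.csv(file.path(dir, "eeg.csv"))
  rr <- read.csv(file.path(dir, "rr.csv"))
  rt <- read.csv(file.path(dir, "rt.csv"))
  names(rt) <- c("time_min", "rt_s", "level")
  structure(list(
    eeg = eeg$value, fs = meta$fs, rr_s = rr$rr_s, rt = rt,
    profile = meta$profile, cfg = NULL
  ), class = "fatigue_session")
}
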