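#' EEG band definitions
#'
#' Canonical frequency bands used throughout: delta 1--4 Hz, theta 4--8 Hz,
#' alpha 8--13 Hz, beta 13--30 Hz, and the broadband EEG range 1--30 Hz.
#' The theta range is not universal in the literature; 4--8 Hz is the
#' standard convention adopted here.
#'
#' @param name Band name; one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"eeg"`, or use [band_def()] for a custom band.
#' @return A `band_def`: list with `name`, `lo_hz`, `hi_hz`.
#' @export
eeg_band <- function(name = c("alpha", "beta", "delta", "theta", "eeg")) {
  name <- match.arg(name)
  lims <- switch(name,
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
    beta = c(13, 30), eeg = c(1, 30))
  band_def(name, lims[1], lims[2])
}

#' @rdname eeg_band
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo_hz < hi_hz`.
#' @export
band_def <- function(name, lo_hz, hi_hz) {
  stopifnot(is.character(name), lo_hz > 0, hi_hz > lo_hz)
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_def")
}

#' Split a signal into fixed-length epochs
#'
#' Non-overlapping consecutive epochs; a trailing partial epoch is dropped.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param epoch_s Epoch length in seconds (default 60).
#' @return List of numeric vectors, each of `epoch_s * fs` samples.
#' @export
epoch_signal <- function(signal, fs, epoch_s = 60) {
  stopifnot(fs > 0, epoch_s > 0)
  n_ep <- floor(length(signal) / (epoch_s * fs))
  if (n_ep < 1) stop("signal shorter than one epoch")
  len <- floor(epoch_s * fs)
  lapply(seq_len(n_ep), function(i) signal[((i - 1) * len + 1):(i * len)])
}

#' Welch power spectral density estimate
#'
#' Mean of modified periodograms over mean-detrended, Hann-windowed,
#' 50%-overlapping segments.  The default 4-s segment gives 0.25 Hz
#' resolution, enough to resolve the 1-Hz band edges used here.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param seg_s Segment length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (one-sided density, units^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5) {
  nseg <- floor(seg_s * fs)
  stopifnot(nseg >= 8, overlap >= 0, overlap < 1)
  if (length(x) < nseg) stop("signal shorter than one Welch segment")
  step <- max(1, floor(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / nseg)  # Hann
  U <- sum(w^2)
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / (fs * U)
    acc <- acc + P[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double all bins except DC (and Nyquist when nseg is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1) * fs / nseg, psd = psd * dbl)
}

#' Band power as the integral of the Welch PSD
#'
#' Trapezoidal integral of the one-sided Welch PSD over `[lo_hz, hi_hz]`,
#' i.e. the band "energy" of the epoch.
#'
#' @param epoch Numeric signal (one epoch).
#' @param fs Sampling rate (Hz).
#' @param band A `band_def` (see [eeg_band()]).
#' @param psd Optional precomputed [welch_psd()] result, to avoid repeating
#'   the spectral estimate when several bands are integrated.
#' @param ... Passed to [welch_psd()].
#' @return Non-negative band power.
#' @export
band_power <- function(epoch, fs, band, psd = NULL, ...) {
  stopifnot(inherits(band, "band_def"))
  if (band$hi_hz > fs / 2) stop("band exceeds the Nyquist frequency")
  if (is.null(psd)) psd <- welch_psd(epoch, fs, ...)
  sel <- psd$freq >= band$lo_hz & psd$freq <= band$hi_hz
  if (sum(sel) < 2) stop("band too narrow for the spectral resolution")
  f <- psd$freq[sel]
  p <- psd$psd[sel]
  sum(diff(f) * (head(p, -1) + p[-1]) / 2)
}

#' Alpha/beta ratio indices
#'
#' @param alpha,beta,theta Non-negative band powers; `beta` must be > 0.
#' @return Named vector: `alpha_over_beta`, `alpha_theta_over_beta`.
#' @export
ratio_features <- function(alpha, beta, theta) {
  if (any(beta <= 0)) stop("beta band power must be positive")
  c(alpha_over_beta = alpha / beta,
    alpha_theta_over_beta = (alpha + theta) / beta)
}

#' RR-interval standard deviation (RRSD)
#'
#' Population standard deviation (denominator N) of an RR-interval series —
#' the classic time-domain heart-rate-variability statistic.
#'
#' @param rr Numeric vector of RR intervals (s), length >= 2.
#' @return RRSD in seconds.
#' @export
rrsd <- function(rr) {
  if (length(rr) < 2) stop("need at least 2 RR intervals")
  sqrt(mean((rr - mean(rr))^2))
}

#' Heart rate from RR intervals
#'
#' @param rr Non-empty numeric vector of RR intervals (s).
#' @return Heart rate in beats per minute, `60 / mean(rr)`.
#' @export
heart_rate <- function(rr) {
  if (length(rr) < 1) stop("empty RR window")
  60 / mean(rr)
}

# Single-level Haar analysis/synthesis.  Odd-length inputs keep their last
# sample untouched at that level.
haar_step <- function(x) {
  n2 <- floor(length(x) / 2)
  ev <- x[2 * seq_len(n2)]
  od <- x[2 * seq_len(n2) - 1]
  list(a = (od + ev) / sqrt(2), d = (od - ev) / sqrt(2),
       tail = if (length(x) %% 2 == 1) x[length(x)] else numeric(0))
}

haar_unstep <- function(a, d, tail) {
  od <- (a + d) / sqrt(2)
  ev <- (a - d) / sqrt(2)
  out <- numeric(2 * length(a))
  out[2 * seq_along(a) - 1] <- od
  out[2 * seq_along(a)] <- ev
  c(out, tail)
}

#' Haar wavelet denoising with soft thresholding
#'
#' Multilevel Haar discrete wavelet transform, soft-thresholding of all
#' detail coefficients, inverse transform.  The default universal threshold
#' is `sigma * sqrt(2 log n)` with `sigma` estimated from the finest-level
#' details by the median absolute deviation (`median(|d1|)/0.6745`).
#'
#' @param signal Numeric vector, length >= `2^level`.
#' @param level Decomposition depth.
#' @param threshold `"universal"` or a non-negative number (0 = pure
#'   round-trip reconstruction).
#' @return Denoised signal, same length as the input.
#' @export
haar_denoise <- function(signal, level = 4, threshold = "universal") {
  n <- length(signal)
  if (n < 2^level) stop("signal too short for the requested level")
  a <- signal
  details <- vector("list", level)
  tails <- vector("list", level)
  for (l in seq_len(level)) {
    st <- haar_step(a)
    a <- st$a
    details[[l]] <- st$d
    tails[[l]] <- st$tail
  }
  thr <- if (identical(threshold, "universal")) {
    sigma <- median(abs(details[[1]])) / 0.6745
    sigma * sqrt(2 * log(n))
  } else {
    stopifnot(is.numeric(threshold), threshold >= 0)
    threshold
  }
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in rev(seq_len(level)))
    a <- haar_unstep(a, soft(details[[l]]), tails[[l]])
  a
}

# canonical physiological factor columns, in reporting order
fatigue_factor_cols <- function() {
  c("alpha_psd", "beta_psd", "delta_psd", "eeg_psd",
    "alpha_over_beta_psd", "alpha_theta_over_beta", "alpha_over_beta",
    "heart_rate_bpm", "rrsd_s")
}

#' Build the per-reaction-time feature table for a session
#'
#' One row per reaction-time sample.  EEG spectral features come from the
#' fixed 60-s epoch containing the sample's timestamp (or the nearest
#' preceding complete epoch when the timestamp falls past the last full
#' epoch); heart rate and RRSD come from the RR intervals in a window of
#' `rr_window_s` seconds ending at the timestamp.  Samples earlier than one
#' full epoch are dropped with a warning.
#'
#' Because a single signal path exists here, the device-style ratio columns
#' and the PSD-derived ratio are computed by the same band-power ratio:
#' `alpha_over_beta` and `alpha_over_beta_psd` are numerically identical
#' but both retained so the table keeps the canonical nine-factor layout.
#'
#' @param session A `fatigue_session` (see [simulate_session()]).
#' @param epoch_s EEG epoch length in seconds.
#' @param rr_window_s RR-statistics window length in seconds.
#' @param session_id Identifier stored in the `session_id` column.
#' @return Data frame of class `feature_table` with columns `session_id`,
#'   `time_min`, the nine physiological factors, `reaction_time_s`, `level`.
#' @export
build_feature_table <- function(session, epoch_s = 60, rr_window_s = 60,
                                session_id = 1L) {
  stopifnot(inherits(session, "fatigue_session"))
  epochs <- epoch_signal(session$eeg, session$fs, epoch_s)
  bands <- lapply(c("alpha", "beta", "delta", "theta", "eeg"), eeg_band)
  names(bands) <- vapply(bands, `[[`, "", "name")
  pow <- t(vapply(epochs, function(ep) {
    psd <- welch_psd(ep, session$fs)
    vapply(bands, function(b) band_power(ep, session$fs, b, psd = psd),
           numeric(1))
  }, numeric(length(bands))))

  rr_end <- cumsum(session$rr_s)         # time (s) at the end of each beat
  rt <- session$rt[order(session$rt$time_min), , drop = FALSE]
  rows <- vector("list", nrow(rt))
  dropped <- 0L
  for (i in seq_len(nrow(rt))) {
    t_s <- rt$time_min[i] * 60
    # epochs cover (start, end]: a sample on a boundary belongs to the
    # epoch just completed, never to one still being recorded
    ep <- min(max(ceiling(t_s / epoch_s), 1), nrow(pow))
    if (t_s < epoch_s) { dropped <- dropped + 1L; next }
    p <- pow[ep, ]
    rr_win <- session$rr_s[rr_end > t_s - rr_window_s & rr_end <= t_s]
    if (length(rr_win) < 2) { dropped <- dropped + 1L; next }
    ab <- p[["alpha"]] / p[["beta"]]
    rows[[i]] <- data.frame(
      session_id = session_id, time_min = rt$time_min[i],
      alpha_psd = p[["alpha"]], beta_psd = p[["beta"]],
      delta_psd = p[["delta"]], eeg_psd = p[["eeg"]],
      alpha_over_beta_psd = ab,
      alpha_theta_over_beta = (p[["alpha"]] + p[["theta"]]) / p[["beta"]],
      alpha_over_beta = ab,
      heart_rate_bpm = heart_rate(rr_win),
      rrsd_s = rrsd(rr_win),
      reaction_time_s = rt$rt_s[i],
      level = rt$level[i]
    )
  }
  if (dropped > 0)
    warning(sprintf("%d reaction-time sample(s) dropped (before first full epoch or empty RR window)",
                    dropped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature tables for every session of a cohort
#'
#' @param cohort List of `fatigue_session`.
#' @param ... Passed to [build_feature_table()].
#' @return A single combined `feature_table`, `session_id` keyed by cohort
#'   position.
#' @export
cohort_feature_table <- function(cohort, ...) {
  tabs <- lapply(seq_along(cohort), function(i)
    build_feature_table(cohort[[i]], session_id = i, ...))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' @param tab A `feature_table`.
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the table.
#' @export
write_feature_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path)
  class(out) <- c("feature_table", "data.frame")
  out
}
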