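#' End-to-end run configuration
#'
#' @param n_subjects Cohort size.
#' @param profile_mix Gender mix passed to [simulate_cohort()].
#' @param sim_overrides Named list of [sim_config()] arguments applied to
#'   every subject (gender/age/seed are set per subject).
#' @param grey A [grey_config()].
#' @param ga A [ga_config()].
#' @param train_n,test_n Row counts of the stratified train/test split
#'   (defaults 142 / 100 of a 242-row selection).
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A `run_config` object.
#' @export
run_config <- function(n_subjects = 5,
                       profile_mix = c(male = 0.6, female = 0.4),
                       sim_overrides = list(),
                       grey = grey_config(),
                       ga = ga_config(),
                       train_n = 142, test_n = 100,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, train_n >= 3, test_n >= 1)
  structure(list(n_subjects = n_subjects, profile_mix = profile_mix,
                 sim_overrides = sim_overrides, grey = grey, ga = ga,
                 train_n = train_n, test_n = test_n,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Stratified-by-level train/test split of (train_n + test_n) rows sampled
# from the table; proportions of each level are preserved by rounding.
split_train_test <- function(tab, train_n, test_n, seed) {
  need <- train_n + test_n
  if (nrow(tab) < need)
    stop(sprintf("feature table has %d rows; %d required", nrow(tab), need))
  set.seed(seed)
  pick <- tab[sample(nrow(tab), need), , drop = FALSE]
  tr_idx <- unlist(lapply(split(seq_len(need), pick$level), function(idx) {
    k <- round(length(idx) * train_n / need)
    k <- max(1, min(k, length(idx) - 1))
    sample(idx, k)
  }))
  # pad/trim to exactly train_n while keeping every level represented
  extra <- setdiff(seq_len(need), tr_idx)
  if (length(tr_idx) > train_n)
    tr_idx <- tr_idx[seq_len(train_n)]
  else if (length(tr_idx) < train_n)
    tr_idx <- c(tr_idx, sample(extra, train_n - length(tr_idx)))
  list(train = pick[sort(tr_idx), , drop = FALSE],
       test = pick[sort(setdiff(seq_len(need), tr_idx)), , drop = FALSE])
}

#' Run the full fatigue-analysis pipeline
#'
#' simulate a cohort -> extract the per-reaction-time feature table ->
#' rank the nine physiological factors against reaction time by grey
#' relational analysis -> train the hierarchical GA-SVM on (reaction time,
#' top-ranked factor) with a stratified 142/100-style split -> evaluate on
#' the held-out rows.  Every stage derives its own seed from the master
#' seed, so a run is a pure function of its configuration.  When `out_dir`
#' is given, each stage's output is persisted (features CSV, grey ranking
#' CSV, model JSON, report JSON).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param top_factor Override the grey-selected classifier input (e.g. to
#'   compare a deliberately weaker factor).
#' @return List with `features`, `grey`, `top_factor`, `model`, `report`,
#'   `test_accuracy`, and the `split`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL,
                    top_factor = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(
    config$n_subjects, config$profile_mix,
    seed = derive_seed(config$seed, "simulate"),
    cfg_fn = function(gender, age_group, rng_seed)
      do.call(sim_config, c(list(gender = gender, age_group = age_group,
                                 rng_seed = rng_seed),
                            config$sim_overrides)))
  feats <- suppressWarnings(cohort_feature_table(cohort))

  gres <- grey_rank_cohort(feats, cfg = config$grey)
  if (is.null(top_factor))
    top_factor <- suppressWarnings(select_top_factor(gres))

  sp <- split_train_test(feats, config$train_n, config$test_n,
                         derive_seed(config$seed, "split"))
  cols <- c("reaction_time_s", top_factor)
  ga <- modify_ga_seed(config$ga, derive_seed(config$seed, "ga"))
  model <- train_hierarchical(sp$train, feature_cols = cols, ga = ga)
  pred <- predict(model, sp$test)
  report <- stage_metrics(confusion_matrix(sp$test$level, pred))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(feats, file.path(out_dir, "features.csv"))
    write.csv(data.frame(factor = names(gres$gamma),
                         gamma = as.numeric(gres$gamma),
                         rank = match(names(gres$gamma), gres$ranking)),
              file.path(out_dir, "grey_ranking.csv"), row.names = FALSE)
    write_model(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(list(matrix = unclass(report$matrix),
                              stage1 = report$stage1,
                              stage2 = report$stage2,
                              top_factor = top_factor,
                              test_accuracy = report$stage1$accuracy),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = feats, grey = gres, top_factor = top_factor,
       model = model, report = report,
       test_accuracy = report$stage1$accuracy, split = sp)
}

#' Reduced configuration for smoke tests
#'
#' A cut-down run (short sessions, small GA) that exercises every stage in
#' well under two minutes on one CPU.
#'
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
quick_run_config <- function(seed = 1L) {
  run_config(
    n_subjects = 2,
    sim_overrides = list(duration_min = 120, period_bounds = c(30, 80)),
    ga = ga_config(pop_size = 8, generations = 5, cv_folds = 3,
                   rng_seed = seed),
    train_n = 45, test_n = 30,
    seed = seed
  )
}
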