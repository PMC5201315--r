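#' Confusion matrix for three mental-state levels
#'
#' @param actual,predicted Equal-length integer vectors over `{1, 2, 3}`.
#' @return 3x3 count matrix, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) == 0 || length(actual) != length(predicted))
    stop("actual and predicted must be nonempty and of equal length")
  if (!all(actual %in% 1:3) || !all(predicted %in% 1:3))
    stop("labels must lie in {1, 2, 3}")
  m <- table(factor(actual, 1:3), factor(predicted, 1:3))
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(actual = paste0("L", 1:3),
                              predicted = paste0("L", 1:3)))
  m
}

rate <- function(num, den) if (den == 0) NA_real_ else num / den

#' Stage-wise classification metrics from a 3x3 confusion matrix
#'
#' Stage 1 treats level 3 (the fatigued state, Category II) as positive and
#' levels 1--2 (Category I) as negative.  Following the reporting convention
#' of hierarchical two-stage classification, a Category-I row counts toward
#' stage-1 specificity only when its *final* level is exact, so
#' `stage1$accuracy` equals the overall three-class accuracy; the
#' false-positive rate counts Category-I rows predicted as level 3.
#' Stage 2 takes level 2 as positive with whole-row denominators (all
#' actual level-1 and level-2 samples); its false-negative rate counts
#' level-2 rows predicted as level 1, and its precision is computed on the
#' Category-I submatrix.  Undefined rates (zero denominators) are returned
#' as `NA`, never as a silent 0.
#'
#' @param m 3x3 confusion matrix (rows = actual, columns = predicted).
#' @return A `confusion_report`: list with `matrix`, `stage1` and `stage2`,
#'   each stage holding `sensitivity`, `specificity`, `accuracy`,
#'   `fp_rate`, `fn_rate`, `precision`.
#' @export
stage_metrics <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)), all(m >= 0))
  total <- sum(m)
  a3 <- sum(m[3, ])               # actual level 3
  aI <- sum(m[1:2, ])             # actual Category I
  s1 <- list(
    sensitivity = rate(m[3, 3], a3),
    specificity = rate(m[1, 1] + m[2, 2], aI),
    accuracy    = rate(m[1, 1] + m[2, 2] + m[3, 3], total),
    fp_rate     = rate(m[1, 3] + m[2, 3], aI),
    fn_rate     = rate(m[3, 1] + m[3, 2], a3),
    precision   = rate(m[3, 3], sum(m[, 3]))
  )
  a2 <- sum(m[2, ]); a1 <- sum(m[1, ])
  s2 <- list(
    sensitivity = rate(m[2, 2], a2),
    specificity = rate(m[1, 1], a1),
    accuracy    = rate(m[1, 1] + m[2, 2], aI),
    fp_rate     = rate(m[1, 2], a1),
    fn_rate     = rate(m[2, 1], a2),
    precision   = rate(m[2, 2], m[1, 2] + m[2, 2])
  )
  structure(list(matrix = m, stage1 = s1, stage2 = s2),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(x$matrix)
  fmt <- function(s) paste(sprintf("%s=%.4f", names(s), unlist(s)),
                           collapse = "  ")
  cat("Stage 1 (level 3 vs levels 1-2):\n  ", fmt(x$stage1), "\n")
  cat("Stage 2 (level 2 vs level 1):\n  ", fmt(x$stage2), "\n")
  invisible(x)
}

#' Reaction-time growth rates across mental-state levels
#'
#' For each subject group (e.g. gender or age band) with per-level mean
#' reaction times, the growth rate from level a to level b is
#' `(mean_b - mean_a) / mean_a`, in percent.  Cross-group averages follow
#' the tabular convention of averaging the two-decimal rounded group rates
#' (half-up), which is how such summary rows are printed.  When exactly two
#' groups are given, per-level between-group gaps are also reported.
#'
#' @param means_by_group Named list of length-3 positive numeric vectors
#'   (per-level means, seconds), or a single length-3 vector.
#' @return A `growth_report`: per-group `l1_l2` and `l1_l3` rates (percent,
#'   unrounded), `average` of the rounded group rates, and (two groups)
#'   `between_group` per-level gaps in percent.
#' @export
growth_rates <- function(means_by_group) {
  if (is.numeric(means_by_group))
    means_by_group <- list(group = means_by_group)
  stopifnot(length(means_by_group) >= 1)
  per <- lapply(means_by_group, function(mu) {
    stopifnot(length(mu) == 3)
    if (any(mu <= 0)) stop("level means must be positive")
    c(l1_l2 = 100 * (mu[2] - mu[1]) / mu[1],
      l1_l3 = 100 * (mu[3] - mu[1]) / mu[1])
  })
  tab <- do.call(rbind, per)
  avg <- c(l1_l2 = mean(round_half_up(tab[, "l1_l2"])),
           l1_l3 = mean(round_half_up(tab[, "l1_l3"])))
  out <- list(rates = tab, average = round_half_up(avg))
  if (length(means_by_group) == 2) {
    a <- means_by_group[[1]]; b <- means_by_group[[2]]
    out$between_group <- 100 * (b - a) / a
  }
  structure(out, class = "growth_report")
}

#' Rolling dispersion ("volatility") of a reaction-time series
#'
#' Rolling variance (or SD) over a sliding window, used to contrast the
#' unstable adaptation period at the start of a drive with the stable
#' middle period.
#'
#' @param rt Numeric reaction-time series.
#' @param window Window length in samples (>= 2).
#' @param statistic `"variance"` (default) or `"sd"`.
#' @return Numeric vector of length `length(rt) - window + 1`.
#' @export
rt_volatility <- function(rt, window, statistic = c("variance", "sd")) {
  statistic <- match.arg(statistic)
  n <- length(rt)
  stopifnot(window >= 2)
  if (n < window) stop("series shorter than the window")
  v <- vapply(seq_len(n - window + 1), function(i)
    var(rt[i:(i + window - 1)]), numeric(1))
  if (statistic == "sd") sqrt(v) else v
}

#' Evaluate predictions and write a JSON report
#'
#' @param actual,predicted Level vectors over `{1, 2, 3}`.
#' @param path Optional JSON output path.
#' @return The `confusion_report` (invisibly when `path` is given).
#' @export
evaluate_predictions <- function(actual, predicted, path = NULL) {
  rep <- stage_metrics(confusion_matrix(actual, predicted))
  if (!is.null(path)) {
    jsonlite::write_json(list(matrix = unclass(rep$matrix),
                              stage1 = rep$stage1, stage2 = rep$stage2),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
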