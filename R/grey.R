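#' Grey relational analysis configuration
#'
#' @param phi Resolution ratio in `(0, 1]`; 0.5 is the customary value and
#'   sharpens the contrast between correlation coefficients.
#' @param preprocess Sequence preprocessing before differencing:
#'   `"init_transform"` (divide by the first element; default),
#'   `"normalize"` (min-max to `[0, 1]`), or `"both"` (initialization then
#'   min-max).
#' @param degree_denominator `"n"` (mean of the coefficients; bounded by 1,
#'   default) or `"n_minus_1"` (sum of the n coefficients divided by n-1,
#'   which exceeds 1 for a perfect match — kept selectable for literal
#'   comparability with sources using that convention).
#' @return A `grey_config` object.
#' @export
grey_config <- function(phi = 0.5,
                        preprocess = c("init_transform", "normalize", "both"),
                        degree_denominator = c("n", "n_minus_1")) {
  stopifnot(phi > 0, phi <= 1)
  structure(list(phi = phi, preprocess = match.arg(preprocess),
                 degree_denominator = match.arg(degree_denominator)),
            class = "grey_config")
}

#' Min-max normalization to [0, 1]
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return `(x - min) / (max - min)`.
#' @export
grey_normalize <- function(x) {
  stopifnot(length(x) >= 2)
  r <- range(x)
  if (diff(r) == 0) stop("constant sequence cannot be min-max normalized")
  (x - r[1]) / (r[2] - r[1])
}

#' Initialization transform
#'
#' Divides a sequence by its first element so every transformed sequence
#' starts at 1 and only relative trajectories are compared.
#'
#' @param x Numeric vector with `x[1] != 0`.
#' @return `x / x[1]`.
#' @export
init_transform <- function(x) {
  if (length(x) < 1 || x[1] == 0)
    stop("first element must be nonzero for the initialization transform")
  x / x[1]
}

grey_preprocess <- function(x, cfg) {
  switch(cfg$preprocess,
         init_transform = init_transform(x),
         normalize = grey_normalize(x),
         both = grey_normalize(init_transform(x)))
}

#' Grey relational degree of factors against a reference sequence
#'
#' For each factor i the pointwise difference sequence
#' `Delta_i(k) = |x0'(k) - xi'(k)|` is formed from the preprocessed
#' reference and factor.  The correlation coefficient at each point is
#' `xi_i(k) = (min_min + phi * max_max) / (Delta_i(k) + phi * max_max)`
#' with the extrema taken jointly over all factors and all points, and the
#' relational degree `gamma_i` averages the coefficients (denominator per
#' configuration).  Factors are ranked by decreasing degree.
#'
#' @param reference Numeric reference sequence (e.g. reaction time).
#' @param factors Named list of numeric sequences, or a data.frame/matrix of
#'   factor columns, all the same length as `reference`.
#' @param cfg A [grey_config()].
#' @return A `grey_result`: list with `xi` (points x factors matrix of
#'   coefficients), `gamma` (named degrees), `ranking` (factor names by
#'   decreasing degree, ties kept in input order), and `cfg`.
#' @export
grey_degree <- function(reference, factors, cfg = grey_config()) {
  if (is.matrix(factors) || is.data.frame(factors))
    factors <- as.list(as.data.frame(factors))
  if (length(factors) == 0) stop("empty factor set")
  if (is.null(names(factors)) || any(names(factors) == ""))
    names(factors) <- paste0("factor", seq_along(factors))
  n <- length(reference)
  stopifnot(n >= 2)
  if (any(vapply(factors, length, 0L) != n))
    stop("all factor sequences must match the reference length")

  ref_p <- grey_preprocess(reference, cfg)
  fac_p <- lapply(factors, grey_preprocess, cfg = cfg)
  delta <- vapply(fac_p, function(f) abs(ref_p - f), numeric(n))
  delta <- matrix(delta, nrow = n,
                  dimnames = list(NULL, names(factors)))
  dmin <- min(delta)
  dmax <- max(delta)
  xi <- if (dmax == 0) {
    matrix(1, n, ncol(delta), dimnames = dimnames(delta))
  } else {
    (dmin + cfg$phi * dmax) / (delta + cfg$phi * dmax)
  }
  denom <- if (cfg$degree_denominator == "n") n else n - 1
  gamma <- colSums(xi) / denom
  ord <- order(-gamma)               # stable: ties keep input order
  structure(list(xi = xi, gamma = gamma,
                 ranking = names(factors)[ord], cfg = cfg),
            class = "grey_result")
}

#' Average grey relational degrees across sessions
#'
#' Runs [grey_degree()] per session of a combined feature table (reference =
#' reaction time) and averages the degrees, the convention when several
#' recordings are analysed as one cohort.
#'
#' @param tab A `feature_table` with a `session_id` column.
#' @param reference_col Reference column name.
#' @param factor_cols Factor column names (default: the nine physiological
#'   factors).
#' @param cfg A [grey_config()].
#' @return A `grey_result` whose `gamma` are cross-session means (with the
#'   per-session degrees in `$per_session`).
#' @export
grey_rank_cohort <- function(tab, reference_col = "reaction_time_s",
                             factor_cols = fatigue_factor_cols(),
                             cfg = grey_config()) {
  stopifnot(all(c("session_id", reference_col, factor_cols) %in% names(tab)))
  per <- lapply(split(tab, tab$session_id), function(d) {
    grey_degree(d[[reference_col]], as.list(d[factor_cols]), cfg)$gamma
  })
  gamma <- colMeans(do.call(rbind, per))
  ord <- order(-gamma)
  structure(list(xi = NULL, gamma = gamma,
                 ranking = names(gamma)[ord], cfg = cfg,
                 per_session = per),
            class = "grey_result")
}

#' Factor preference order for tie-breaking
#'
#' When two factors achieve exactly the same relational degree — which
#' happens structurally here because the device-style and PSD-derived
#' alpha/beta columns share one computation path — the winner is taken from
#' a fixed documented order: composite ratio indices first (plain
#' alpha/beta ahead of its PSD-labelled duplicate), then raw band powers,
#' then cardiac factors.
#'
#' @return Character vector of factor names, most preferred first.
#' @export
fatigue_factor_preference <- function() {
  c("alpha_over_beta", "alpha_over_beta_psd", "alpha_theta_over_beta",
    "eeg_psd", "alpha_psd", "beta_psd", "delta_psd",
    "rrsd_s", "heart_rate_bpm")
}

#' Select the factor with the greatest relational degree
#'
#' @param result A `grey_result`.
#' @param prefer Character vector giving the tie-break order (most preferred
#'   first); factors not listed keep their input order.  Defaults to
#'   [fatigue_factor_preference()] when all its names are present, else the
#'   input order.
#' @return The name of the arg-max factor.  Exact ties emit a warning and
#'   are resolved by `prefer`.
#' @export
select_top_factor <- function(result, prefer = NULL) {
  stopifnot(inherits(result, "grey_result"), length(result$gamma) >= 1)
  g <- result$gamma
  top <- names(g)[g == max(g)]
  if (length(top) > 1) {
    if (is.null(prefer) && all(names(g) %in% fatigue_factor_preference()))
      prefer <- fatigue_factor_preference()
    if (!is.null(prefer)) {
      hit <- prefer[prefer %in% top]
      if (length(hit)) top <- hit
    }
    warning(sprintf("tied grey relational degrees (%s); selecting '%s'",
                    paste(names(g)[g == max(g)], collapse = ", "), top[1]))
  }
  top[1]
}
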