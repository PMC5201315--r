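# Independent step-by-step oracles, written before the implementations they
# check and kept deliberately naive (explicit loops, no shared code paths).

# Grey relational degree, recomputed literally: initialization transform,
# pointwise absolute differences, two-level min/max, coefficient, degree.
grey_oracle <- function(reference, factors, phi = 0.5,
                        denominator = c("n", "n_minus_1")) {
  denominator <- match.arg(denominator)
  n <- length(reference)
  ref_t <- numeric(n)
  for (k in 1:n) ref_t[k] <- reference[k] / reference[1]
  fac_t <- lapply(factors, function(x) {
    out <- numeric(n)
    for (k in 1:n) out[k] <- x[k] / x[1]
    out
  })
  delta <- lapply(fac_t, function(f) {
    d <- numeric(n)
    for (k in 1:n) d[k] <- abs(ref_t[k] - f[k])
    d
  })
  dmin <- Inf; dmax <- -Inf
  for (d in delta) for (k in 1:n) {
    if (d[k] < dmin) dmin <- d[k]
    if (d[k] > dmax) dmax <- d[k]
  }
  gamma <- numeric(length(factors))
  for (i in seq_along(factors)) {
    s <- 0
    for (k in 1:n)
      s <- s + (dmin + phi * dmax) / (delta[[i]][k] + phi * dmax)
    gamma[i] <- if (denominator == "n") s / n else s / (n - 1)
  }
  names(gamma) <- names(factors)
  gamma
}

# Stage metrics recomputed by direct counting over label pairs.
stage_metrics_oracle <- function(actual, predicted) {
  n <- length(actual)
  cnt <- function(cond) sum(cond)
  a3 <- cnt(actual == 3)
  aI <- cnt(actual %in% 1:2)
  s1 <- list(
    sensitivity = cnt(actual == 3 & predicted == 3) / a3,
    specificity = cnt(actual %in% 1:2 & predicted == actual) / aI,
    accuracy    = cnt(predicted == actual) / n,
    fp_rate     = cnt(actual %in% 1:2 & predicted == 3) / aI,
    fn_rate     = cnt(actual == 3 & predicted %in% 1:2) / a3,
    precision   = cnt(actual == 3 & predicted == 3) / cnt(predicted == 3)
  )
  a2 <- cnt(actual == 2); a1 <- cnt(actual == 1)
  s2 <- list(
    sensitivity = cnt(actual == 2 & predicted == 2) / a2,
    specificity = cnt(actual == 1 & predicted == 1) / a1,
    accuracy    = cnt(actual %in% 1:2 & predicted == actual) / aI,
    fp_rate     = cnt(actual == 1 & predicted == 2) / a1,
    fn_rate     = cnt(actual == 2 & predicted == 1) / a2,
    precision   = cnt(actual == 2 & predicted == 2) /
      cnt(actual %in% 1:2 & predicted == 2)
  )
  list(stage1 = s1, stage2 = s2)
}

# The published 3x3 worked-example confusion matrix.
reference_confusion <- function() {
  matrix(c(40, 6, 0,
           4, 25, 1,
           0, 3, 21), nrow = 3, byrow = TRUE,
         dimnames = list(actual = paste0("L", 1:3),
                         predicted = paste0("L", 1:3)))
}

# Shared short session fixture (two thirds of the default length scaled
# down; periods rescaled to keep all three levels present).
short_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_session(sim_config(duration_min = 120,
                                            period_bounds = c(30, 80),
                                            rng_seed = 11L))
    cache
  }
})
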