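estimator_workers <- function() {
  list(nonparametric = .est_nonparametric,
       robust_boxcox = .est_robust_boxcox,
       iterative_trim = .est_iterative_trim,
       bhattacharya = .est_bhattacharya)
}

resolve_estimator <- function(estimator) {
  if (is.function(estimator)) return(estimator)
  workers <- estimator_workers()
  if (!estimator %in% names(workers))
    ri_error("unknown_method",
             paste0("unknown estimation method: ", estimator))
  workers[[estimator]]
}

# Core percentile bootstrap; assumes the RNG stream is already positioned.
bootstrap_ci_core <- function(values, worker, settings) {
  B <- settings$bootstrap_B
  if (B < 2L)
    ri_error("invalid_B", "bootstrap needs at least 2 resamples")
  n <- length(values)
  lows <- ups <- rep(NA_real_, B)
  failed <- 0L
  for (b in seq_len(B)) {
    xb <- values[sample.int(n, n, replace = TRUE)]
    est <- tryCatch(worker(xb, settings), rilab_error = function(e) NULL)
    if (is.null(est)) { failed <- failed + 1L; next }
    lows[b] <- est$lower
    ups[b] <- est$upper
  }
  if (failed > B / 2)
    ri_error("unstable_bootstrap",
             sprintf("%d of %d bootstrap resamples failed", failed, B))
  a <- 1 - settings$ci_level
  ok <- !is.na(lows)
  list(ci_lower = ri_quantile(lows[ok], c(a / 2, 1 - a / 2)),
       ci_upper = ri_quantile(ups[ok], c(a / 2, 1 - a / 2)),
       n_failed = failed, B = B)
}

#' Bootstrap confidence intervals for reference limits
#'
#' Percentile bootstrap of the two reference limits: `B` resamples with
#' replacement (same n) are drawn, the estimator is applied to each
#' (resamples on which it errors are dropped and counted), and the
#' `ci_level` central percentile interval of the resampled lower limits --
#' and likewise of the upper limits -- is returned. Deterministic for a
#' given `rng_seed`.
#'
#' @param values numeric vector the estimator is bootstrapped on.
#' @param estimator method name (`"nonparametric"`, `"robust_boxcox"`,
#'   `"iterative_trim"`, `"bhattacharya"`) or a function
#'   `(values, settings) -> list(lower, upper)`.
#' @param settings an [estimator_settings()] bundle (`bootstrap_B`,
#'   `ci_level`, `rng_seed`).
#' @return list with `ci_lower` and `ci_upper` (each `c(low, high)`),
#'   `n_failed` and `B`.
#' @export
bootstrap_ci <- function(values, estimator, settings = estimator_settings()) {
  worker <- resolve_estimator(estimator)
  if (!is.null(settings$rng_seed)) set.seed(settings$rng_seed)
  bootstrap_ci_core(as.numeric(values), worker, settings)
}
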