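# Sample quantile at rank p*(n+1) with linear interpolation between order
# statistics, clamped to the observed extremes -- the CLSI nonparametric
# recipe (stats::quantile type 6).
ri_quantile <- function(x, p) {
  stats::quantile(x, probs = p, type = 6, names = FALSE)
}

.est_nonparametric <- function(values, settings) {
  n <- length(values)
  if (n < 2L)
    ri_error("insufficient_sample",
             sprintf("nonparametric estimation needs n >= 2, got %d", n))
  alpha <- 1 - settings$coverage
  lims <- ri_quantile(values, c(alpha / 2, 1 - alpha / 2))
  list(lower = lims[1], upper = lims[2],
       diagnostics = list(ranks = c(alpha / 2, 1 - alpha / 2) * (n + 1)))
}

#' Direct nonparametric reference interval
#'
#' The standard direct method: the lower and upper reference limits are the
#' `alpha/2` and `1 - alpha/2` sample quantiles (`alpha = 1 - coverage`),
#' computed at rank `p * (n + 1)` with linear interpolation between order
#' statistics and clamped to the observed extremes.
#'
#' This wrapper estimates from the values as given; the full pipeline with
#' outlier screening, minimum-n gate and bootstrap CIs is [estimate_ri()].
#'
#' @param values numeric vector of reference values (n >= 2).
#' @param coverage central fraction covered, default 0.95.
#' @return a [reference_interval] object (without CIs).
#' @export
nonparametric_ri <- function(values, coverage = 0.95) {
  settings <- estimator_settings(coverage = coverage)
  est <- .est_nonparametric(as.numeric(values), settings)
  new_reference_interval(est$lower, est$upper, method = "nonparametric",
                         n_used = length(values), coverage = coverage,
                         diagnostics = est$diagnostics)
}
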