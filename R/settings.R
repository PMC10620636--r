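#' Estimator settings
#'
#' Bundle of tuning parameters shared by the reference-interval estimators,
#' the outlier screen, the bootstrap and the federated path.
#'
#' @param sigma_k half-width, in sample standard deviations, of the outlier
#'   screening range around the sample mean. Default 3 (the 3-sigma rule).
#' @param coverage central fraction of the reference population the interval
#'   should span. Default 0.95, i.e. the 2.5th--97.5th percentile interval.
#' @param ci_level confidence level for the bootstrap CIs of the interval
#'   limits. Default 0.90.
#' @param bootstrap_B number of bootstrap resamples. Default 500.
#' @param rng_seed integer seed for all randomness in a single estimation
#'   call (bootstrap resampling, count obfuscation). `NULL` continues the
#'   current RNG stream; the seed actually used is recorded in diagnostics.
#' @param min_n minimum reference-sample size below which estimation is
#'   refused. Default 120.
#' @param trim_z half-width, in SDs, of the central region retained at each
#'   step of the iterative trimming estimator. Default 1.645 (central 90%).
#' @param tol relative convergence tolerance on sigma for iterative trimming.
#' @param max_iter iteration cap for iterative trimming.
#' @param bhat_min_count minimum bin count for a bin pair to contribute a
#'   point to the Bhattacharya log-difference plot. Default 5.
#' @param bhat_min_run minimum number of consecutive decreasing points that
#'   form a candidate linear segment. Default 4.
#' @param bhat_r2_min minimum OLS R-squared for a segment to qualify as a
#'   Gaussian component. Default 0.95.
#' @param bhat_noise_z Poisson-noise allowance (in standard errors) when
#'   judging whether successive log-count differences are decreasing; 0
#'   demands strict decrease. Default 2.
#' @param bhat_target_bins bin-count target when the Bhattacharya method
#'   derives its own binning from the sample range. Coarser than the
#'   federated default: with fine bins the per-bin log-count step drowns
#'   in counting noise. Default 20 (bin width roughly half the component
#'   SD at typical sample sizes).
#' @param target_bins target number of histogram bins used when a bin
#'   specification is derived from a data range. Default 50.
#' @param site_min_n optional per-site minimum sample size in federated mode;
#'   sites below it are excluded from aggregation. Default 0 (off).
#' @return an object of class `estimator_settings` (a validated list).
#' @export
estimator_settings <- function(sigma_k = 3, coverage = 0.95, ci_level = 0.90,
                               bootstrap_B = 500, rng_seed = NULL,
                               min_n = 120, trim_z = 1.645, tol = 1e-6,
                               max_iter = 100, bhat_min_count = 5,
                               bhat_min_run = 4, bhat_r2_min = 0.95,
                               bhat_noise_z = 2, bhat_target_bins = 20,
                               target_bins = 50, site_min_n = 0) {
  stopifnot(sigma_k > 0, coverage > 0, coverage < 1,
            ci_level > 0, ci_level < 1, min_n >= 1, trim_z > 0,
            tol > 0, max_iter >= 1, bhat_min_count >= 1, bhat_min_run >= 2,
            bhat_r2_min > 0, bhat_r2_min <= 1, bhat_noise_z >= 0,
            bhat_target_bins >= 2, target_bins >= 2, site_min_n >= 0)
  structure(
    list(sigma_k = sigma_k, coverage = coverage, ci_level = ci_level,
         bootstrap_B = as.integer(bootstrap_B), rng_seed = rng_seed,
         min_n = as.integer(min_n), trim_z = trim_z, tol = tol,
         max_iter = as.integer(max_iter),
         bhat_min_count = bhat_min_count, bhat_min_run = as.integer(bhat_min_run),
         bhat_r2_min = bhat_r2_min, bhat_noise_z = bhat_noise_z,
         bhat_target_bins = as.integer(bhat_target_bins),
         target_bins = as.integer(target_bins),
         site_min_n = as.integer(site_min_n)),
    class = "estimator_settings"
  )
}

#' @export
print.estimator_settings <- function(x, ...) {
  cat("Reference-interval estimator settings:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

# Merge user overrides (a plain named list, e.g. from a YAML config) into a
# settings object, re-validating through the constructor.
merge_settings <- function(settings, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(settings)
  args <- unclass(settings)
  bad <- setdiff(names(overrides), names(args))
  if (length(bad))
    ri_error("invalid_setting", paste0("unknown setting(s): ",
                                       paste(bad, collapse = ", ")))
  args[names(overrides)] <- overrides
  do.call(estimator_settings, args)
}
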