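# Bhattacharya decomposition: for a Gaussian component binned at uniform
# width h, the successive log-count differences y_i = ln n_{i+1} - ln n_i
# fall on a straight line when plotted against the center of bin i+1, with
# slope b = -h / sigma^2. Fitting a line to each such segment gives
#   sigma^2 = -h/b - h^2/12   (Sheppard's correction for binning)
#   mu      = -a/b - h/2
# where a is the intercept.

.est_bhattacharya <- function(values, settings, bin_spec = NULL) {
  x <- as.numeric(values)
  if (is.null(bin_spec)) {
    if (min(x) == max(x))
      ri_error("insufficient_bins", "sample has zero range")
    bin_spec <- choose_bin_spec(min(x), max(x), settings$bhat_target_bins)
  }
  tab <- build_frequency_table(x, bin_spec, site_id = "local")
  counts <- tab$counts
  nb <- length(counts)
  if (nb < settings$bhat_min_run + 1L)
    ri_error("insufficient_bins",
             sprintf("%d bins available, need at least %d", nb,
                     settings$bhat_min_run + 1L))
  h <- bin_spec$width
  centers_upper <- bin_spec$low_edge + (seq_len(nb - 1L) + 0.5) * h
  valid <- counts[-nb] >= settings$bhat_min_count &
    counts[-1] >= settings$bhat_min_count
  y <- rep(NA_real_, nb - 1L)
  y[valid] <- log(counts[-1][valid]) - log(counts[-nb][valid])

  segments <- decreasing_runs(y, counts, settings$bhat_noise_z)
  comps <- list()
  for (seg in segments) {
    if (length(seg) < settings$bhat_min_run) next
    xs <- centers_upper[seg]
    ys <- y[seg]
    # log-count differences are heteroskedastic (var ~ 1/n_i + 1/n_{i+1});
    # fit and judge the segment by inverse-variance weighted least squares
    w <- 1 / (1 / counts[seg] + 1 / counts[seg + 1L])
    fit <- stats::lm.wfit(cbind(1, xs), ys, w)
    a <- fit$coefficients[1]
    b <- fit$coefficients[2]
    if (!is.finite(b) || b >= 0) next
    ybar <- sum(w * ys) / sum(w)
    r2 <- 1 - sum(w * fit$residuals^2) / sum(w * (ys - ybar)^2)
    if (!is.finite(r2) || r2 < settings$bhat_r2_min) next
    sigma2 <- -h / b - h^2 / 12
    if (sigma2 <= 0) next
    mu <- -a / b - h / 2
    sigma <- sqrt(sigma2)
    # Share of the total counts implied by the fitted Gaussian: scale the
    # observed counts over the segment's bins by their fitted probabilities.
    bins <- unique(c(seg, seg + 1L))       # y_i links bins i and i+1
    edges_lo <- bin_spec$low_edge + (bins - 1L) * h
    p <- stats::pnorm((edges_lo + h - mu) / sigma) -
      stats::pnorm((edges_lo - mu) / sigma)
    implied_n <- sum(counts[bins]) / sum(p)
    comps[[length(comps) + 1L]] <- data.frame(
      first_bin = bins[1], n_points = length(seg), mu = mu, sigma = sigma,
      r2 = r2, implied_n = implied_n)
  }
  if (length(comps) == 0L)
    ri_error("no_component_found",
             "no linear segment qualified as a Gaussian component")
  comp_table <- do.call(rbind, comps)
  comp_table$share <- comp_table$implied_n / tab$n_total
  main <- comp_table[which.max(comp_table$implied_n), ]
  z <- stats::qnorm(1 - (1 - settings$coverage) / 2)
  list(lower = main$mu - z * main$sigma, upper = main$mu + z * main$sigma,
       diagnostics = list(component_table = comp_table, mu = main$mu,
                          sigma = main$sigma, bin_width = h,
                          n_bins = nb))
}

# Maximal runs of consecutive indices i where y[i] is defined and y is
# decreasing along the run. Decrease is judged against the Poisson counting
# noise of the log-count differences: the step y[i+1] - y[i] has variance
# approximately 1/n_i + 4/n_{i+1} + 1/n_{i+2}, and a step is accepted while
# it stays below noise_z standard errors above zero. With noise-free counts
# this reduces to strict decrease; with sampled counts it keeps a
# component's descending limb in one segment instead of fragmenting it on
# within-noise jitter.
decreasing_runs <- function(y, counts, noise_z = 2) {
  runs <- list()
  i <- 1L
  n <- length(y)
  step_ok <- function(j) {
    se <- sqrt(1 / counts[j] + 4 / counts[j + 1L] + 1 / counts[j + 2L])
    y[j + 1L] - y[j] < noise_z * se
  }
  while (i <= n) {
    if (is.na(y[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(y[j + 1L]) && step_ok(j)) j <- j + 1L
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

#' Bhattacharya reference interval
#'
#' Indirect method that decomposes a binned mixed-population distribution
#' into Gaussian subcomponents. Data are binned at uniform width; for each
#' adjacent bin pair with adequate counts the successive log-count
#' difference is computed; maximal strictly decreasing runs of these points
#' that are long enough and sufficiently linear (OLS R-squared) are read as
#' Gaussian components, whose mean and SD follow from the fitted slope and
#' intercept (with Sheppard's correction for binning). The main component
#' -- the one implying the largest share of the total counts -- defines the
#' reference interval `mu +/- z * sigma`.
#'
#' @param values numeric vector of reference values.
#' @param settings an [estimator_settings()] bundle (`bhat_min_count`,
#'   `bhat_min_run`, `bhat_r2_min`, `target_bins`, `coverage`).
#' @param bin_spec optional [bin_spec()]; by default one is chosen from the
#'   sample range with [choose_bin_spec()].
#' @return a [reference_interval] object (without CIs); diagnostics record
#'   the full component table.
#' @export
bhattacharya_ri <- function(values, settings = estimator_settings(),
                            bin_spec = NULL) {
  est <- .est_bhattacharya(values, settings, bin_spec)
  new_reference_interval(est$lower, est$upper, method = "bhattacharya",
                         n_used = length(values),
                         coverage = settings$coverage,
                         diagnostics = est$diagnostics)
}
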