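#' Federated reference-interval estimation
#'
#' Simulates the "no copy, no move" multi-site path: every site screens its
#' own values with the local 3-sigma filter, bins them on a shared
#' specification, optionally obfuscates the counts, and emits a frequency
#' table -- the only object that crosses the site boundary. The tables are
#' aggregated (plaintext summation standing in for encrypted aggregation),
#' the minimum-n gate is applied to the aggregate total, and the reference
#' limits are read off the joint histogram by interpolated quantiles.
#' Confidence intervals come from a histogram bootstrap: multinomial
#' resamples of the aggregate counts.
#'
#' The bin specification is shared up front (e.g. from a per-analyte
#' catalogue). When none is given it is negotiated from per-site
#' `(min, max)` summaries of the locally filtered values -- the only other
#' statistic a site then reveals.
#'
#' @param sites named list of numeric vectors: each site's cleaned,
#'   deduplicated, query-filtered values. Raw values are used only inside
#'   each site's local closure; cross-site computation happens in
#'   [federated_estimate_from_tables()].
#' @param settings an [estimator_settings()] bundle (`sigma_k`, `min_n`,
#'   `site_min_n`, `coverage`, `ci_level`, `bootstrap_B`, `target_bins`,
#'   `rng_seed`).
#' @param epsilon optional obfuscation scale passed to
#'   [obfuscate_counts()]; `NULL` (default) releases exact counts.
#' @param spec optional shared [bin_spec()] catalogue entry.
#' @param loinc analyte code attached to the result.
#' @return a [reference_interval] with `mode = "federated"` and the
#'   aggregate table in diagnostics, or an [ri_refusal].
#' @export
federated_estimate <- function(sites, settings = estimator_settings(),
                               epsilon = NULL, spec = NULL,
                               loinc = NA_character_) {
  stopifnot(is.list(sites), length(sites) >= 1L)
  seed <- settings$rng_seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)

  # --- local, per-site computation (never leaves the site) ---------------
  filtered <- lapply(sites, function(v) three_sigma_filter(v, settings$sigma_k)$kept)
  filtered <- Filter(function(v) length(v) >= max(1L, settings$site_min_n),
                     filtered)
  if (length(filtered) == 0L)
    return(ri_refusal(0L, settings$min_n, loinc = loinc, mode = "federated"))
  if (is.null(spec)) {
    lows <- vapply(filtered, min, numeric(1))
    highs <- vapply(filtered, max, numeric(1))
    lo <- min(lows)
    hi <- max(highs)
    if (lo == hi) hi <- lo + abs(lo) * 1e-6 + 1e-9
    spec <- choose_bin_spec(lo, hi, settings$target_bins)
  }
  site_ids <- names(filtered)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_along(filtered))
  tables <- Map(function(v, id) {
    t <- build_frequency_table(v, spec, site_id = id)
    if (!is.null(epsilon)) t <- obfuscate_counts(t, epsilon)
    t
  }, filtered, site_ids)

  # --- cross-site computation: frequency tables only ---------------------
  res <- federated_estimate_from_tables(tables, settings, loinc = loinc)
  if (!is_refused(res)) res$diagnostics$rng_seed <- seed
  res
}

#' Estimate a reference interval from released frequency tables
#'
#' The cross-site half of [federated_estimate()]. Its signature is the
#' structural privacy contract of the protocol: it accepts
#' [frequency_table()] objects only, so no raw patient-level value can
#' reach the aggregation side.
#'
#' @param tables list of per-site [frequency_table()] objects sharing one
#'   bin specification.
#' @param settings an [estimator_settings()] bundle.
#' @param loinc analyte code attached to the result.
#' @return a [reference_interval] (`mode = "federated"`,
#'   `method = "histogram"`) or an [ri_refusal].
#' @export
federated_estimate_from_tables <- function(tables,
                                           settings = estimator_settings(),
                                           loinc = NA_character_) {
  if (!all(vapply(tables, inherits, logical(1), "frequency_table")))
    ri_error("raw_data_at_boundary",
             "cross-site estimation accepts frequency tables only")
  agg <- aggregate_frequency_tables(tables)
  if (agg$n_total < settings$min_n)
    return(ri_refusal(agg$n_total, settings$min_n, loinc = loinc,
                      mode = "federated"))
  alpha <- 1 - settings$coverage
  p <- c(alpha / 2, 1 - alpha / 2)
  lims <- quantiles_from_histogram(agg, p)
  boot <- histogram_bootstrap_ci(agg, p, settings)
  new_reference_interval(
    lims[1], lims[2], method = "histogram", n_used = agg$n_total,
    n_outliers_removed = 0L, coverage = settings$coverage,
    ci_lower = boot$ci_lower, ci_upper = boot$ci_upper,
    ci_level = settings$ci_level, loinc = loinc, mode = "federated",
    diagnostics = list(frequency_table = agg, n_sites = length(tables),
                       bin_width = agg$bin_spec$width,
                       obfuscated = agg$obfuscated)
  )
}

# Multinomial bootstrap of the aggregate histogram: resample n_total counts
# from the observed bin proportions, recompute the interpolated quantiles.
histogram_bootstrap_ci <- function(agg, p, settings) {
  B <- settings$bootstrap_B
  if (B < 2L)
    ri_error("invalid_B", "bootstrap needs at least 2 resamples")
  lows <- ups <- rep(NA_real_, B)
  prob <- agg$counts / sum(agg$counts)
  for (b in seq_len(B)) {
    cb <- as.integer(stats::rmultinom(1, agg$n_total, prob))
    tb <- frequency_table(agg$bin_spec, cb, site_id = "AGGREGATE")
    q <- quantiles_from_histogram(tb, p)
    lows[b] <- q[1]
    ups[b] <- q[2]
  }
  a <- 1 - settings$ci_level
  list(ci_lower = ri_quantile(lows, c(a / 2, 1 - a / 2)),
       ci_upper = ri_quantile(ups, c(a / 2, 1 - a / 2)))
}
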