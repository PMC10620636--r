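#' Uniform-width bin specification
#'
#' Bin edges sit at `low_edge + i * width` with half-open bins
#' `[edge, edge + width)`. Widths are restricted to the 1-2-5 ladder
#' (`{1, 2, 5} * 10^k`), the "rounded bin size width" that keeps released
#' histograms coarse enough to hinder re-identification, and `low_edge` is
#' an integer multiple of the width (anchor 0).
#'
#' @param width bin width on the 1-2-5 ladder.
#' @param low_edge left edge of the first bin (multiple of `width`).
#' @param n_bins number of bins.
#' @param ladder enforce the 1-2-5 width restriction (default). It exists
#'   for released federated histograms; method-local binning that never
#'   crosses a site boundary (e.g. a catalogue width of 0.25 mmol/L for a
#'   Bhattacharya fit) may opt out.
#' @return an object of class `bin_spec`.
#' @export
bin_spec <- function(width, low_edge, n_bins, ladder = TRUE) {
  stopifnot(width > 0, n_bins >= 1)
  mant <- width / 10^floor(log10(width))
  if (ladder && min(abs(mant - c(1, 2, 5))) > 1e-9)
    ri_error("invalid_bin_width",
             sprintf("width %g is not on the 1-2-5 ladder", width))
  if (abs(low_edge / width - round(low_edge / width)) > 1e-9)
    ri_error("invalid_bin_width",
             sprintf("low_edge %g is not a multiple of width %g",
                     low_edge, width))
  structure(list(width = width, anchor = 0, low_edge = low_edge,
                 n_bins = as.integer(n_bins)),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf("Bin spec: %d bins of width %g over [%g, %g)\n",
              x$n_bins, x$width, x$low_edge,
              x$low_edge + x$n_bins * x$width))
  invisible(x)
}

bin_spec_equal <- function(a, b) {
  identical(a$width, b$width) && identical(a$low_edge, b$low_edge) &&
    identical(a$n_bins, b$n_bins)
}

#' Choose a rounded bin specification for a data range
#'
#' Picks the smallest width on the 1-2-5 ladder that is at least
#' `(high - low) / target_bins` (rounding up, so the bin count never
#' exceeds the target: coarser bins release less information), anchors the
#' grid at 0, and extends it to cover `high`.
#'
#' @param low,high the range to cover, `low < high`.
#' @param target_bins upper bound on the number of bins, default 50.
#' @return a [bin_spec()].
#' @export
choose_bin_spec <- function(low, high, target_bins = 50) {
  if (!(low < high))
    ri_error("empty_range", "need low < high to choose a bin width")
  raw <- (high - low) / target_bins
  k <- floor(log10(raw))
  width <- NA_real_
  for (step in c(1, 2, 5, 10)) {
    cand <- step * 10^k
    if (cand >= raw * (1 - 1e-12)) { width <- cand; break }
  }
  low_edge <- width * floor(low / width)
  n_bins <- floor((high - low_edge) / width) + 1L
  bin_spec(width, low_edge, n_bins)
}

#' Build a per-site frequency table
#'
#' Bins values into the shared specification's half-open bins
#' `[edge, edge + width)`. In federated use the specification is fixed
#' across sites, so it is never auto-extended: values outside the covered
#' range are clamped into the edge bins and counted in `n_clamped`.
#'
#' @param values non-empty numeric vector of a site's (locally filtered)
#'   query results.
#' @param spec a shared [bin_spec()].
#' @param site_id identifier of the emitting site.
#' @return an object of class `frequency_table`: the only object a site
#'   emits in federated mode (bin spec, counts, total, site id, obfuscation
#'   flag).
#' @export
build_frequency_table <- function(values, spec, site_id) {
  stopifnot(inherits(spec, "bin_spec"))
  values <- as.numeric(values)
  if (length(values) == 0L)
    ri_error("empty_site_sample", "cannot build a frequency table from no values")
  idx <- floor((values - spec$low_edge) / spec$width) + 1L
  n_clamped <- sum(idx < 1L | idx > spec$n_bins)
  idx <- pmin(pmax(idx, 1L), spec$n_bins)
  counts <- tabulate(idx, nbins = spec$n_bins)
  frequency_table(spec, counts, site_id = site_id, n_clamped = n_clamped)
}

#' Construct a frequency table
#'
#' @param spec a [bin_spec()].
#' @param counts non-negative integer counts, one per bin.
#' @param site_id emitting site, or `"AGGREGATE"`.
#' @param obfuscated have the counts been perturbed?
#' @param n_clamped values clamped into edge bins at build time.
#' @return an object of class `frequency_table`.
#' @export
frequency_table <- function(spec, counts, site_id, obfuscated = FALSE,
                            n_clamped = 0L) {
  stopifnot(inherits(spec, "bin_spec"), length(counts) == spec$n_bins,
            all(counts >= 0))
  structure(list(bin_spec = spec, counts = as.integer(counts),
                 n_total = as.integer(sum(counts)), site_id = site_id,
                 obfuscated = obfuscated, n_clamped = as.integer(n_clamped)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("Frequency table [%s]%s: n = %d in %d bins of width %g\n",
              x$site_id, if (x$obfuscated) " (obfuscated)" else "",
              x$n_total, x$bin_spec$n_bins, x$bin_spec$width))
  invisible(x)
}

#' Obfuscate released counts
#'
#' Perturbs each bin count with independent two-sided geometric (discrete
#' Laplace) noise with parameter `exp(-epsilon)` -- the discrete analogue of
#' the Laplace mechanism -- then clamps at zero. Smaller `epsilon` means
#' more noise; as `epsilon` grows the noise collapses to zero and the table
#' is returned unchanged.
#'
#' @param table a [frequency_table()].
#' @param epsilon positive noise scale parameter.
#' @param seed integer seed making the perturbation reproducible.
#' @return a new `frequency_table` with perturbed counts, `obfuscated` set
#'   and `n_total` recomputed.
#' @export
obfuscate_counts <- function(table, epsilon, seed = NULL) {
  stopifnot(inherits(table, "frequency_table"), epsilon > 0)
  if (!is.null(seed)) set.seed(seed)
  p <- 1 - exp(-epsilon)
  nb <- length(table$counts)
  noise <- stats::rgeom(nb, p) - stats::rgeom(nb, p)
  frequency_table(table$bin_spec, pmax(table$counts + noise, 0L),
                  site_id = table$site_id, obfuscated = TRUE,
                  n_clamped = table$n_clamped)
}

#' Aggregate per-site frequency tables
#'
#' Element-wise summation of counts over tables sharing an identical bin
#' specification -- the plaintext stand-in for the encrypted aggregation of
#' the production protocol. Re-binning is never attempted: a mismatched
#' specification is an error.
#'
#' @param tables list of [frequency_table()] objects on one shared spec.
#' @return the aggregate `frequency_table` with `site_id = "AGGREGATE"`.
#' @export
aggregate_frequency_tables <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "frequency_table")))
  spec <- tables[[1]]$bin_spec
  for (t in tables[-1])
    if (!bin_spec_equal(spec, t$bin_spec))
      ri_error("bin_spec_mismatch",
               "all sites must bin on the identical shared specification")
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  frequency_table(spec, counts, site_id = "AGGREGATE",
                  obfuscated = any(vapply(tables, `[[`, logical(1), "obfuscated")),
                  n_clamped = sum(vapply(tables, `[[`, integer(1), "n_clamped")))
}

#' Quantile of a binned distribution
#'
#' Inverts the cumulative counts of a frequency table with uniform-within-bin
#' linear interpolation: returns the value at which the cumulative count
#' reaches `p * n_total`.
#'
#' @param table a [frequency_table()] with positive total count.
#' @param p probabilities in (0, 1).
#' @return numeric vector of quantile values, monotone in `p`.
#' @export
quantiles_from_histogram <- function(table, p) {
  stopifnot(inherits(table, "frequency_table"), all(p > 0), all(p < 1))
  counts <- table$counts
  if (sum(counts) == 0L)
    ri_error("empty_histogram", "no counts to take quantiles from")
  spec <- table$bin_spec
  cum <- cumsum(counts)
  n <- cum[length(cum)]
  vapply(p, function(pp) {
    target <- pp * n
    i <- which(cum >= target)[1]
    below <- if (i == 1L) 0 else cum[i - 1L]
    spec$low_edge + (i - 1L) * spec$width +
      spec$width * (target - below) / counts[i]
  }, numeric(1))
}

#' Pairwise additive masking of site counts (demonstration stub)
#'
#' Demonstrates the aggregation-only contract of the federated protocol:
#' each pair of sites agrees on a random mask added to one side and
#' subtracted from the other, so individual released vectors are
#' uninformative noise while their sum equals the true aggregate exactly.
#' This illustrates the interface of secure aggregation; it provides no
#' actual security (masks are generated centrally here).
#'
#' @param tables list of [frequency_table()] objects on one shared spec.
#' @param seed integer seed for the masks.
#' @return list with `masked` (list of numeric count vectors, one per site)
#'   and `aggregate` (the exact aggregate `frequency_table` recovered by
#'   summing them).
#' @export
masked_aggregation <- function(tables, seed = NULL) {
  stopifnot(length(tables) >= 1L)
  spec <- tables[[1]]$bin_spec
  for (t in tables[-1])
    if (!bin_spec_equal(spec, t$bin_spec))
      ri_error("bin_spec_mismatch", "shared bin spec required")
  if (!is.null(seed)) set.seed(seed)
  k <- length(tables)
  nb <- spec$n_bins
  masked <- lapply(tables, function(t) as.numeric(t$counts))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      m <- stats::rnorm(nb, 0, 1e3)
      masked[[i]] <- masked[[i]] + m
      masked[[j]] <- masked[[j]] - m
    }
  }
  total <- round(Reduce(`+`, masked))
  list(masked = masked,
       aggregate = frequency_table(spec, as.integer(total),
                                   site_id = "AGGREGATE"))
}
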