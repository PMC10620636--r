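#' Reference interval objects
#'
#' @description
#' The result of [estimate_ri()] and [federated_estimate()]: lower and upper
#' reference limits in analyte units, optional bootstrap confidence
#' intervals for each limit, the method used, sample bookkeeping and
#' method-specific diagnostics. Supports `print()`, `summary()`, `coef()`
#' (the two limits), `confint()` (the bootstrap CIs) and `plot()`.
#'
#' @param lower,upper reference limits, `lower <= upper`.
#' @param method one of `"nonparametric"`, `"robust_boxcox"`,
#'   `"iterative_trim"`, `"bhattacharya"`, or `"histogram"` (federated).
#' @param n_used number of values the estimate was computed from (after
#'   outlier removal).
#' @param coverage central fraction the interval targets.
#' @param n_outliers_removed values removed by the outlier screen.
#' @param ci_lower,ci_upper `c(low, high)` bootstrap CIs for each limit, or
#'   `NULL`.
#' @param ci_level confidence level of the CIs, or `NULL`.
#' @param loinc analyte code, if known.
#' @param mode `"pooled"` or `"federated"`.
#' @param diagnostics named list of method diagnostics.
#' @return an object of class `reference_interval`.
#' @name reference_interval
#' @export
new_reference_interval <- function(lower, upper, method, n_used,
                                   coverage = 0.95,
                                   n_outliers_removed = 0L,
                                   ci_lower = NULL, ci_upper = NULL,
                                   ci_level = NULL, loinc = NA_character_,
                                   mode = "pooled", diagnostics = list()) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  stopifnot(is.finite(lower), is.finite(upper), lower <= upper)
  if (!is.null(ci_lower)) stopifnot(length(ci_lower) == 2L,
                                    ci_lower[1] <= ci_lower[2])
  if (!is.null(ci_upper)) stopifnot(length(ci_upper) == 2L,
                                    ci_upper[1] <= ci_upper[2])
  structure(
    list(lower = lower, upper = upper, method = method,
         n_used = as.integer(n_used),
         n_outliers_removed = as.integer(n_outliers_removed),
         coverage = coverage, ci_lower = ci_lower, ci_upper = ci_upper,
         ci_level = ci_level, loinc = loinc, mode = mode,
         diagnostics = diagnostics),
    class = "reference_interval"
  )
}

#' Estimate a reference interval from a reference sample
#'
#' The full estimation pipeline for one stratified cohort: refuse if the
#' sample holds fewer than `min_n` patients; otherwise screen outliers with
#' the single-pass `sigma_k`-sigma filter, apply the selected direct or
#' indirect estimation method to the surviving values, and attach
#' percentile-bootstrap confidence intervals for both limits (resampling
#' the post-filter sample).
#'
#' @param sample a [reference_sample()] from [apply_query()], or a plain
#'   numeric vector.
#' @param method `"nonparametric"` (direct), or one of the indirect methods
#'   `"robust_boxcox"`, `"iterative_trim"`, `"bhattacharya"`. Method choice
#'   is explicit: no automatic modality detection is attempted.
#' @param settings an [estimator_settings()] bundle.
#' @return a [reference_interval], or an [ri_refusal] when `n < min_n`
#'   (a typed return value, not an error).
#' @examples
#' set.seed(1)
#' estimate_ri(rnorm(500, 100, 4), method = "nonparametric",
#'             settings = estimator_settings(bootstrap_B = 50, rng_seed = 1))
#' @export
estimate_ri <- function(sample,
                        method = c("nonparametric", "robust_boxcox",
                                   "iterative_trim", "bhattacharya"),
                        settings = estimator_settings()) {
  method <- match.arg(method)
  loinc <- NA_character_
  if (inherits(sample, "reference_sample")) {
    loinc <- sample$loinc
    values <- sample$values
  } else {
    values <- as.numeric(sample)
  }
  if (length(values) < settings$min_n)
    return(ri_refusal(length(values), settings$min_n, loinc = loinc))

  seed <- settings$rng_seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)

  filt <- three_sigma_filter(values, settings$sigma_k)
  worker <- resolve_estimator(method)
  est <- worker(filt$kept, settings)
  boot <- bootstrap_ci_core(filt$kept, worker, settings)

  diagnostics <- est$diagnostics
  diagnostics$rng_seed <- seed
  diagnostics$bootstrap_failed <- boot$n_failed
  if (!is.null(filt$note)) diagnostics$outlier_note <- filt$note

  new_reference_interval(
    est$lower, est$upper, method = method,
    n_used = length(filt$kept),
    n_outliers_removed = length(filt$removed),
    coverage = settings$coverage,
    ci_lower = boot$ci_lower, ci_upper = boot$ci_upper,
    ci_level = settings$ci_level, loinc = loinc,
    diagnostics = diagnostics
  )
}

#' @export
print.reference_interval <- function(x, digits = 4, ...) {
  cat(sprintf("Reference interval (%s, %s mode)%s\n", x$method, x$mode,
              if (is.na(x$loinc)) "" else sprintf(", LOINC %s", x$loinc)))
  cat(sprintf("  central %.0f%%: [%s, %s]\n", 100 * x$coverage,
              format(x$lower, digits = digits),
              format(x$upper, digits = digits)))
  if (!is.null(x$ci_lower))
    cat(sprintf("  %.0f%% CI lower limit: [%s, %s]\n", 100 * x$ci_level,
                format(x$ci_lower[1], digits = digits),
                format(x$ci_lower[2], digits = digits)))
  if (!is.null(x$ci_upper))
    cat(sprintf("  %.0f%% CI upper limit: [%s, %s]\n", 100 * x$ci_level,
                format(x$ci_upper[1], digits = digits),
                format(x$ci_upper[2], digits = digits)))
  cat(sprintf("  n used = %d (outliers removed: %d)\n",
              x$n_used, x$n_outliers_removed))
  invisible(x)
}

#' @export
summary.reference_interval <- function(object, ...) {
  print(object, ...)
  d <- object$diagnostics
  if (length(d)) {
    cat("  diagnostics:\n")
    for (nm in names(d)) {
      v <- d[[nm]]
      if (is.data.frame(v)) {
        cat(sprintf("    %s:\n", nm))
        print(v, row.names = FALSE)
      } else {
        cat(sprintf("    %-18s %s\n", nm,
                    paste(format(v, digits = 5), collapse = ", ")))
      }
    }
  }
  invisible(object)
}

#' @export
coef.reference_interval <- function(object, ...) {
  c(lower = object$lower, upper = object$upper)
}

#' @export
confint.reference_interval <- function(object, parm, level, ...) {
  if (is.null(object$ci_lower))
    return(NULL)
  out <- rbind(lower = object$ci_lower, upper = object$ci_upper)
  colnames(out) <- paste0(100 * c((1 - object$ci_level) / 2,
                                  1 - (1 - object$ci_level) / 2), " %")
  out
}

#' Plot a reference interval
#'
#' Draws the sample distribution (a histogram of `values`, or the
#' aggregated frequency table stored by the federated path) with the
#' reference limits and, when present, their bootstrap confidence bands.
#'
#' @param x a [reference_interval].
#' @param values optional numeric vector to histogram behind the limits.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.reference_interval <- function(x, values = NULL, ...) {
  tab <- x$diagnostics$frequency_table
  if (is.null(values) && !is.null(tab)) {
    edges <- tab$bin_spec$low_edge + (0:tab$bin_spec$n_bins) * tab$bin_spec$width
    mids <- edges[-1] - tab$bin_spec$width / 2
    graphics::plot(mids, tab$counts, type = "h", lwd = 3,
                   xlab = if (is.na(x$loinc)) "value" else x$loinc,
                   ylab = "count", main = "Aggregated frequency table", ...)
  } else if (!is.null(values)) {
    graphics::hist(values, breaks = 40, col = "grey85", border = "white",
                   xlab = if (is.na(x$loinc)) "value" else x$loinc,
                   main = sprintf("Reference interval (%s)", x$method), ...)
  } else {
    graphics::plot(c(x$lower, x$upper), c(0, 0), type = "n",
                   xlab = "value", ylab = "", yaxt = "n",
                   main = sprintf("Reference interval (%s)", x$method))
  }
  graphics::abline(v = c(x$lower, x$upper), col = "firebrick", lwd = 2)
  if (!is.null(x$ci_lower))
    graphics::abline(v = c(x$ci_lower, x$ci_upper), col = "firebrick",
                     lty = 3)
  invisible(x)
}

#' Serialize an estimation result to JSON
#'
#' Writes the result (interval or refusal) in a stable JSON layout:
#' `{loinc, method, n_used, n_outliers_removed, lower, upper,
#' ci_lower: [l, u], ci_upper: [l, u], refused, mode, diagnostics}`.
#'
#' @param x a [reference_interval] or [ri_refusal].
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
ri_to_json <- function(x, path = NULL) {
  if (is_refused(x)) {
    obj <- list(refused = TRUE, n = x$n, min_n = x$min_n,
                loinc = x$loinc, mode = x$mode)
  } else {
    diag <- x$diagnostics
    diag$frequency_table <- NULL    # not part of the result payload
    diag$component_table <- NULL
    obj <- list(loinc = x$loinc, method = x$method, n_used = x$n_used,
                n_outliers_removed = x$n_outliers_removed,
                lower = x$lower, upper = x$upper,
                ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                ci_level = x$ci_level, coverage = x$coverage,
                refused = FALSE, mode = x$mode, diagnostics = diag)
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
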