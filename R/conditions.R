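#' Signal a classed rilab error
#'
#' All recoverable failure modes in the package raise conditions of class
#' `c("rilab_<reason>", "rilab_error", "error")` so callers can branch on the
#' reason programmatically instead of matching message text.
#'
#' @param reason short machine-readable tag, e.g. `"insufficient_sample"`.
#' @param message human-readable message.
#' @param ... extra fields stored on the condition.
#' @keywords internal
#' @noRd
ri_error <- function(reason, message, ...) {
  cond <- structure(
    class = c(paste0("rilab_", reason), "rilab_error", "error", "condition"),
    list(message = message, call = sys.call(-1), reason = reason, ...)
  )
  stop(cond)
}

#' Typed refusal for under-sized reference samples
#'
#' Estimating a reference interval from fewer than `min_n` patients is refused
#' rather than attempted; the refusal is an ordinary return value (not an
#' error) carrying the observed sample size and the threshold, so pipelines
#' can distinguish "too few patients" from a failure.
#'
#' @param n observed sample size.
#' @param min_n the minimum-sample-size threshold in force.
#' @param loinc analyte code, if known.
#' @param mode `"pooled"` or `"federated"`.
#' @return an object of class `ri_refusal`.
#' @export
ri_refusal <- function(n, min_n, loinc = NA_character_, mode = "pooled") {
  structure(
    list(refused = TRUE, n = as.integer(n), min_n = as.integer(min_n),
         loinc = loinc, mode = mode),
    class = "ri_refusal"
  )
}

#' Was the estimation refused?
#'
#' @param x result of [estimate_ri()] or [federated_estimate()].
#' @return `TRUE` for an [ri_refusal], `FALSE` otherwise.
#' @export
is_refused <- function(x) inherits(x, "ri_refusal")

#' @export
print.ri_refusal <- function(x, ...) {
  cat(sprintf(
    "Reference interval estimation refused: n = %d < minimum %d%s (%s mode)\n",
    x$n, x$min_n,
    if (is.na(x$loinc)) "" else sprintf(" [LOINC %s]", x$loinc),
    x$mode
  ))
  invisible(x)
}
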