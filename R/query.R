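#' Cohort stratification query
#'
#' A query selects the reference cohort for one analyte by patient factors
#' (age range, sex, diagnosis history) and analytical factors (analyzer and
#' test-kit identifiers).
#'
#' The age interval is closed on both ends (`[55, 60]` includes 55- and
#' 60-year-olds); disjoint age strata should therefore be constructed as
#' e.g. `[50, 54]`, `[55, 59]`. ICD matching is prefix-based on normalized
#' codes (dot removed, uppercased), so including `"E11"` covers `"E11.9"`.
#' Records with sex `other` or `unknown` match only when those levels are
#' explicitly listed in `sexes`.
#'
#' @param loinc analyte LOINC code.
#' @param age_min,age_max closed age interval in years.
#' @param sexes subset of `c("female", "male", "other", "unknown")`.
#' @param icd_include ICD-10 prefixes; a patient must carry at least one
#'   matching diagnosis (empty = no constraint).
#' @param icd_exclude ICD-10 prefixes; a patient must carry none.
#' @param analyzer_id,kit_id optional exact-match device identifiers.
#' @return an object of class `cohort_query`.
#' @export
cohort_query <- function(loinc, age_min = 0, age_max = Inf,
                         sexes = c("female", "male"),
                         icd_include = character(), icd_exclude = character(),
                         analyzer_id = NULL, kit_id = NULL) {
  stopifnot(is.character(loinc), length(loinc) == 1L, age_min <= age_max,
            all(sexes %in% sex_levels()))
  structure(
    list(loinc = loinc, age_min = age_min, age_max = age_max,
         sexes = unique(sexes),
         icd_include = as.character(icd_include),
         icd_exclude = as.character(icd_exclude),
         analyzer_id = analyzer_id, kit_id = kit_id),
    class = "cohort_query"
  )
}

#' @export
print.cohort_query <- function(x, ...) {
  cat(sprintf("Cohort query: LOINC %s, age [%s, %s], sex {%s}\n",
              x$loinc, format(x$age_min), format(x$age_max),
              paste(x$sexes, collapse = ", ")))
  if (length(x$icd_include))
    cat("  ICD include:", paste(x$icd_include, collapse = ", "), "\n")
  if (length(x$icd_exclude))
    cat("  ICD exclude:", paste(x$icd_exclude, collapse = ", "), "\n")
  if (!is.null(x$analyzer_id)) cat("  analyzer:", x$analyzer_id, "\n")
  if (!is.null(x$kit_id)) cat("  kit:", x$kit_id, "\n")
  invisible(x)
}

#' Read a cohort query from JSON
#'
#' @param path path to a JSON file with keys matching [cohort_query()]
#'   arguments.
#' @return a `cohort_query`.
#' @export
read_cohort_query <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_query))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    ri_error("invalid_query", paste0("unknown query field(s): ",
                                     paste(bad, collapse = ", ")))
  do.call(cohort_query, obj)
}

#' Write a cohort query to JSON
#'
#' @param q a `cohort_query`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_query <- function(q, path) {
  jsonlite::write_json(unclass(q), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

icd_prefix_match <- function(dx, prefixes) {
  # row-wise: does any diagnosis start with any normalized prefix?
  if (length(prefixes) == 0L) return(rep(FALSE, nrow(dx)))
  norm <- matrix(icd_normalize(dx), nrow = nrow(dx))
  norm[!nzchar(dx)] <- ""
  pref <- icd_normalize(prefixes)
  hit <- matrix(FALSE, nrow = nrow(dx), ncol = ncol(dx))
  for (p in pref)
    hit <- hit | (nzchar(norm) & startsWith(norm, p))
  rowSums(hit) > 0
}

#' Apply a cohort query to cleaned measurements
#'
#' Filters records by analyte, the closed age interval, sex set, diagnosis
#' include/exclude prefixes and device identifiers, and returns the
#' surviving values as a reference sample with full filter provenance.
#' An empty result (`n = 0`) is valid, not an error.
#'
#' @param records cleaned, per-case deduplicated measurement data frame.
#' @param q a [cohort_query()].
#' @return an object of class `reference_sample`: list with `loinc`,
#'   `values`, `n` and a `provenance` record of per-filter survivor counts.
#' @export
apply_query <- function(records, q) {
  stopifnot(inherits(q, "cohort_query"))
  counts <- c(input = nrow(records))
  keep <- records$loinc == q$loinc
  counts["loinc"] <- sum(keep)
  keep <- keep & records$age_years >= q$age_min & records$age_years <= q$age_max
  counts["age"] <- sum(keep)
  keep <- keep & records$sex %in% q$sexes
  counts["sex"] <- sum(keep)
  dx <- dx_matrix(records)
  if (length(q$icd_include))
    keep <- keep & icd_prefix_match(dx, q$icd_include)
  if (length(q$icd_exclude))
    keep <- keep & !icd_prefix_match(dx, q$icd_exclude)
  counts["icd"] <- sum(keep)
  if (!is.null(q$analyzer_id))
    keep <- keep & records$analyzer_id == q$analyzer_id
  if (!is.null(q$kit_id))
    keep <- keep & records$kit_id == q$kit_id
  counts["device"] <- sum(keep)
  reference_sample(records$value[keep], loinc = q$loinc,
                   provenance = list(query = q, counts = counts))
}

#' Construct a reference sample
#'
#' @param values finite numeric values surviving query and cleaning.
#' @param loinc analyte code.
#' @param provenance record of the filters that produced the sample.
#' @return an object of class `reference_sample`.
#' @export
reference_sample <- function(values, loinc = NA_character_,
                             provenance = list()) {
  values <- as.numeric(values)
  stopifnot(all(is.finite(values)))
  structure(list(loinc = loinc, values = values, n = length(values),
                 provenance = provenance),
            class = "reference_sample")
}

#' @export
print.reference_sample <- function(x, ...) {
  cat(sprintf("Reference sample: LOINC %s, n = %d\n", x$loinc, x$n))
  if (x$n > 0)
    cat(sprintf("  range [%.4g, %.4g], median %.4g\n",
                min(x$values), max(x$values), stats::median(x$values)))
  invisible(x)
}
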