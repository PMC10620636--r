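#' @name measurements
#' @title Harmonized laboratory measurement records
#'
#' @description
#' Measurement collections are plain data frames in a fixed column layout:
#' `patient_id`, `case_id`, `site_id`, `loinc`, `value`, `unit`, `timestamp`
#' (ISO-8601), `age_years`, `sex` (one of female/male/other/unknown),
#' `dx1`..`dx5` (up to five ICD-10-GM diagnosis codes ordered by billing
#' relevance), `analyzer_id`, `kit_id`. Empty strings encode missing
#' optional fields. Age is carried in years: 3-decimal precision below 18,
#' whole years at 18 and above.
NULL

measurement_columns <- function() {
  c("patient_id", "case_id", "site_id", "loinc", "value", "unit",
    "timestamp", "age_years", "sex", paste0("dx", 1:5),
    "analyzer_id", "kit_id")
}

sex_levels <- function() c("female", "male", "other", "unknown")

# Syntactic ICD-10-GM shape: letter + two digits, optional dot + 1-2
# alphanumerics. Validation is case-insensitive on the letter part.
icd_is_valid <- function(code) {
  grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$", toupper(trimws(code)))
}

# Normalized form used for prefix matching and code-list lookups:
# uppercased, dot removed.
icd_normalize <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

dx_matrix <- function(records) {
  as.matrix(records[, paste0("dx", 1:5), drop = FALSE])
}

parse_timestamps <- function(x) {
  x <- trimws(x)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  fb <- is.na(out)
  if (any(fb))
    out[fb] <- as.POSIXct(x[fb], tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  fb <- is.na(out)
  if (any(fb))
    out[fb] <- as.POSIXct(x[fb], tz = "UTC", format = "%Y-%m-%d")
  out
}

#' Read laboratory measurements from CSV
#'
#' Reads the package's measurement CSV dialect (UTF-8, header row, RFC-4180
#' quoting, empty string = missing). Rows whose `value` or `age_years` cannot
#' be parsed as numbers are dropped with their line numbers reported in a
#' message; all other validation is left to [clean_measurements()].
#'
#' A dataset must carry a single unit string per LOINC code: units are
#' assumed pre-harmonized upstream, and encountering more than one distinct
#' non-empty unit for one analyte is an error (`rilab_unit_mismatch`) --
#' there is no silent conversion.
#'
#' @param path path to a CSV file.
#' @return a measurement data frame (see [measurements]).
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(measurement_columns(), names(raw))
  if (length(missing_cols))
    ri_error("missing_column",
             paste0("missing_column: ", paste(missing_cols, collapse = ", ")))
  raw <- raw[, measurement_columns(), drop = FALSE]
  value <- suppressWarnings(as.numeric(raw$value))
  age <- suppressWarnings(as.numeric(raw$age_years))
  bad <- (is.na(value) & nzchar(raw$value)) | (is.na(age) & nzchar(raw$age_years))
  if (any(bad)) {
    message(sprintf("read_measurements: rejected %d malformed row(s) at line(s) %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
    raw <- raw[!bad, , drop = FALSE]
    value <- value[!bad]
    age <- age[!bad]
  }
  out <- raw
  out$value <- value
  out$age_years <- age
  rownames(out) <- NULL
  check_units(out)
  out
}

check_units <- function(records) {
  has_unit <- nzchar(records$unit)
  if (!any(has_unit)) return(invisible(records))
  tab <- unique(records[has_unit, c("loinc", "unit")])
  dup <- tab$loinc[duplicated(tab$loinc)]
  if (length(dup))
    ri_error("unit_mismatch",
             paste0("more than one unit observed for LOINC ",
                    paste(unique(dup), collapse = ", "),
                    "; units must be harmonized before loading"))
  invisible(records)
}

#' Write laboratory measurements to CSV
#'
#' Inverse of [read_measurements()]: `read_measurements(write_measurements(x))`
#' reproduces `x` for valid data.
#'
#' @param records a measurement data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records[, measurement_columns(), drop = FALSE], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Clean laboratory measurement records
#'
#' Removes records with missing or clearly erroneous entries: missing
#' identifiers or values, non-finite values, invalid sex or negative age
#' (reason `"malformed"`); negative values for analytes that do not admit
#' them (reason `"negative_value"`); and diagnosis codes that fail
#' syntactic ICD-10-GM validation or, when a code list is supplied, are
#' absent from it (reason `"invalid_icd"`). Each rejected record carries
#' exactly one primary reason, assigned in the order above. Cleaning never
#' raises on bad values and is idempotent.
#'
#' @param records a measurement data frame.
#' @param allow_negative character vector of LOINC codes for which negative
#'   values are legitimate (e.g. base excess).
#' @param valid_icd optional character vector of admissible ICD-10-GM codes
#'   (compared on the normalized, dot-free form); `NULL` keeps validation
#'   purely syntactic.
#' @return a list with components `kept` (clean records) and `rejected`
#'   (records with an added `reason` column).
#' @export
clean_measurements <- function(records, allow_negative = character(),
                               valid_icd = NULL) {
  n <- nrow(records)
  if (n == 0L) return(list(kept = records,
                           rejected = cbind(records, reason = character(0))))
  malformed <-
    !nzchar(records$patient_id) | !nzchar(records$case_id) |
    !nzchar(records$loinc) | !nzchar(records$timestamp) |
    is.na(records$value) | !is.finite(records$value) |
    is.na(records$age_years) | records$age_years < 0 |
    !(records$sex %in% sex_levels())

  negative <- !malformed & records$value < 0 &
    !(records$loinc %in% allow_negative)

  dx <- dx_matrix(records)
  present <- nzchar(dx)
  bad_dx <- present & !matrix(icd_is_valid(dx), nrow = n)
  if (!is.null(valid_icd)) {
    ok_set <- icd_normalize(valid_icd)
    bad_dx <- bad_dx | (present & !matrix(icd_normalize(dx) %in% ok_set, nrow = n))
  }
  invalid_icd <- !malformed & !negative & rowSums(bad_dx) > 0

  reason <- rep(NA_character_, n)
  reason[malformed] <- "malformed"
  reason[negative] <- "negative_value"
  reason[invalid_icd] <- "invalid_icd"
  drop <- !is.na(reason)

  rejected <- records[drop, , drop = FALSE]
  rejected$reason <- reason[drop]
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Keep the first measurement per administrative case and analyte
#'
#' Repeated measurements within one hospital admission are dominated by
#' therapeutic intervention; only the earliest measurement of each analyte
#' per administrative case is retained. Ties on the timestamp keep the
#' record occurring first in input order (stable). Output is sorted by
#' `(case_id, loinc)` for determinism.
#'
#' @param records a measurement data frame with parseable timestamps.
#' @return the deduplicated measurement data frame.
#' @export
first_per_case <- function(records) {
  if (nrow(records) == 0L) return(records)
  ts <- parse_timestamps(records$timestamp)
  ord <- order(records$case_id, records$loinc, ts, seq_len(nrow(records)))
  sorted <- records[ord, , drop = FALSE]
  key <- paste(sorted$case_id, sorted$loinc, sep = "\r")
  out <- sorted[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
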