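#' Analyte generative model
#'
#' Describes how one analyte's values arise in a mixed clinical population:
#' a physiological component (Gaussian or lognormal, with a linear age
#' effect centered at age 50 and per-sex offsets, both on the value scale)
#' plus zero or more pathological components, each affecting a fraction of
#' patients and probabilistically linked to an ICD-10 diagnosis prefix
#' (`p_icd < 1` makes billing diagnoses an imperfect proxy for pathology,
#' as in real data). Device metadata are drawn from a weighted list.
#'
#' @param loinc analyte LOINC code.
#' @param unit unit string.
#' @param physio list: `family` (`"gaussian"` or `"lognormal"`), `mu`,
#'   `sigma` (log-scale parameters for lognormal), optional `age_slope`
#'   (units per year) and `sex_offset` (named numeric).
#' @param patho list of components, each a list with `fraction` (of
#'   patients), `icd_prefix`, optional `p_icd` (default 0.8), and either
#'   `shift` (added to a physiological draw) or its own `family`/`mu`/`sigma`.
#' @param devices data frame with columns `analyzer_id`, `kit_id`, `weight`,
#'   or `NULL`.
#' @param allow_negative are negative values legitimate for this analyte?
#' @return an object of class `analyte_model`.
#' @export
analyte_model <- function(loinc, unit, physio, patho = list(),
                          devices = NULL, allow_negative = FALSE) {
  stopifnot(physio$family %in% c("gaussian", "lognormal"), physio$sigma > 0)
  if (is.null(physio$age_slope)) physio$age_slope <- 0
  if (is.null(physio$sex_offset)) physio$sex_offset <- numeric(0)
  so <- stats::setNames(rep(0, 4), sex_levels())
  so[names(physio$sex_offset)] <- physio$sex_offset
  physio$sex_offset <- so
  fractions <- vapply(patho, function(p) p$fraction, numeric(1))
  if (length(fractions) && (any(fractions < 0) || sum(fractions) >= 1))
    ri_error("invalid_config", "patho fractions must be >= 0 and sum to < 1")
  patho <- lapply(patho, function(p) {
    if (is.null(p$p_icd)) p$p_icd <- 0.8
    p
  })
  if (!is.null(devices)) {
    stopifnot(all(c("analyzer_id", "kit_id", "weight") %in% names(devices)))
    devices$weight <- devices$weight / sum(devices$weight)
  }
  structure(list(loinc = loinc, unit = unit, physio = physio, patho = patho,
                 devices = devices, allow_negative = allow_negative),
            class = "analyte_model")
}

#' Site configuration for the synthetic generator
#'
#' @param site_id site identifier; prefixes all patient and case ids.
#' @param n_patients number of patients to simulate.
#' @param age age distribution spec: `list(dist = "uniform", min, max)`,
#'   `list(dist = "normal", mean, sd, min, max)` or
#'   `list(dist = "fixed", value)`. Ages follow the data convention:
#'   whole years at >= 18, 3-decimal years below.
#' @param sex_props named proportions over female/male/other/unknown
#'   (must sum to 1).
#' @param cases_per_patient `list(dist = "fixed", value)` or
#'   `list(dist = "poisson", lambda)` (drawn as `1 + rpois(lambda)`).
#' @param measurements_per_case same forms as `cases_per_patient`.
#' @param analytes list of [analyte_model()] objects.
#' @param seed integer RNG seed for this site's stream.
#' @return an object of class `site_config`.
#' @export
site_config <- function(site_id, n_patients,
                        age = list(dist = "uniform", min = 18, max = 90),
                        sex_props = c(female = 0.49, male = 0.49,
                                      other = 0.01, unknown = 0.01),
                        cases_per_patient = list(dist = "fixed", value = 1),
                        measurements_per_case = list(dist = "fixed", value = 1),
                        analytes = list(), seed = 1L) {
  stopifnot(n_patients >= 1, length(analytes) >= 1,
            all(vapply(analytes, inherits, logical(1), "analyte_model")))
  if (abs(sum(sex_props) - 1) > 1e-8)
    ri_error("invalid_config", "sex_props must sum to 1")
  miss <- setdiff(names(sex_props), sex_levels())
  if (length(miss))
    ri_error("invalid_config", paste0("unknown sex level(s): ",
                                      paste(miss, collapse = ", ")))
  props <- stats::setNames(rep(0, 4), sex_levels())
  props[names(sex_props)] <- sex_props
  structure(list(site_id = site_id, n_patients = as.integer(n_patients),
                 age = age, sex_props = props,
                 cases_per_patient = cases_per_patient,
                 measurements_per_case = measurements_per_case,
                 analytes = analytes, seed = as.integer(seed)),
            class = "site_config")
}

format_age <- function(age) {
  age <- pmax(age, 0)
  ifelse(age >= 18, floor(age), round(age, 3))
}

draw_ages <- function(spec, n) {
  a <- switch(spec$dist,
    uniform = stats::runif(n, spec$min, spec$max),
    normal = pmin(pmax(stats::rnorm(n, spec$mean, spec$sd),
                       spec$min %||% 0), spec$max %||% 105),
    fixed = rep(spec$value, n),
    ri_error("invalid_config", paste0("unknown age dist: ", spec$dist))
  )
  format_age(a)
}

draw_counts <- function(spec, n) {
  switch(spec$dist,
    fixed = rep(as.integer(spec$value), n),
    poisson = 1L + stats::rpois(n, spec$lambda),
    ri_error("invalid_config", paste0("unknown count dist: ", spec$dist))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

benign_icd_pool <- function() {
  c("Z00.0", "Z76.8", "Z51.8", "I10", "J06.9", "M54.5", "K29.7", "R51")
}

#' Sample a site's patients
#'
#' Draws the patient-level covariates (age in the data's precision
#' convention, sex from the configured proportions) for a site. Used
#' internally by [generate_site_dataset()]; exposed for covariate-level
#' checks.
#'
#' @param config a [site_config()].
#' @return data frame with `patient_id`, `age_years`, `sex`.
#' @export
sample_patients <- function(config) {
  n <- config$n_patients
  data.frame(
    patient_id = sprintf("%s-P%05d", config$site_id, seq_len(n)),
    age_years = draw_ages(config$age, n),
    sex = sample(sex_levels(), n, replace = TRUE, prob = config$sex_props),
    stringsAsFactors = FALSE
  )
}

draw_component_values <- function(model, comp_idx, ages, sexes) {
  n <- length(comp_idx)
  ph <- model$physio
  draw_family <- function(family, mu, sigma, m) {
    if (family == "lognormal") exp(stats::rnorm(m, mu, sigma))
    else stats::rnorm(m, mu, sigma)
  }
  v <- numeric(n)
  base_idx <- comp_idx == 0L
  v[base_idx] <- draw_family(ph$family, ph$mu, ph$sigma, sum(base_idx))
  for (k in seq_along(model$patho)) {
    sel <- comp_idx == k
    if (!any(sel)) next
    p <- model$patho[[k]]
    if (!is.null(p$family)) {
      v[sel] <- draw_family(p$family, p$mu, p$sigma, sum(sel))
    } else {
      v[sel] <- draw_family(ph$family, ph$mu, ph$sigma, sum(sel)) + p$shift
    }
  }
  v <- v + ph$age_slope * (ages - 50) + ph$sex_offset[sexes]
  if (!model$allow_negative) v <- pmax(v, 0.001)
  round(unname(v), 4)
}

#' Generate one site's synthetic measurement dataset
#'
#' Simulates a mixed clinical population for every analyte in the
#' configuration: each patient is assigned a pathological component with
#' its configured fraction (or none), draws values from that component,
#' and carries the component's ICD prefix as a diagnosis with probability
#' `p_icd`; remaining diagnosis slots are filled from a benign code pool.
#' Values get the linear age effect and sex offset, are floored at a small
#' positive value unless the analyte admits negatives, and are rounded to
#' 4 decimals. Output is bit-identical for a given seed.
#'
#' The returned data frame carries a `truth` attribute (patient/analyte
#' component assignment) for validation; it is not part of the CSV dialect.
#'
#' @param config a [site_config()].
#' @return a measurement data frame (see [measurements]).
#' @export
generate_site_dataset <- function(config) {
  stopifnot(inherits(config, "site_config"))
  set.seed(config$seed)
  patients <- sample_patients(config)
  n_pat <- nrow(patients)
  n_cases <- draw_counts(config$cases_per_patient, n_pat)

  # per-patient, per-analyte mixture component (0 = physiological)
  truth <- list()
  dx_per_patient <- rep(list(character(0)), n_pat)
  comp <- list()
  for (a in seq_along(config$analytes)) {
    model <- config$analytes[[a]]
    fr <- vapply(model$patho, function(p) p$fraction, numeric(1))
    comp[[a]] <- sample(0:length(model$patho), n_pat, replace = TRUE,
                        prob = c(1 - sum(fr), fr))
    truth[[a]] <- data.frame(patient_id = patients$patient_id,
                             loinc = model$loinc, component = comp[[a]],
                             stringsAsFactors = FALSE)
    has_icd <- if (length(model$patho) == 0L) rep(FALSE, n_pat) else
      comp[[a]] > 0L &
        stats::runif(n_pat) < vapply(pmax(comp[[a]], 1L), function(k)
          model$patho[[k]]$p_icd, numeric(1))
    for (i in which(has_icd)) {
      prefix <- model$patho[[comp[[a]][i]]]$icd_prefix
      code <- if (grepl("^[A-Z][0-9]{2}$", prefix))
        paste0(prefix, ".", sample(0:9, 1)) else prefix
      dx_per_patient[[i]] <- c(dx_per_patient[[i]], code)
    }
  }
  # pad with benign codes so most patients carry some history
  n_benign <- sample(0:2, n_pat, replace = TRUE)
  for (i in seq_len(n_pat)) {
    if (n_benign[i] > 0L)
      dx_per_patient[[i]] <- c(dx_per_patient[[i]],
                               sample(benign_icd_pool(), n_benign[i]))
    dx_per_patient[[i]] <- utils::head(unique(dx_per_patient[[i]]), 5L)
  }
  dx_mat <- t(vapply(dx_per_patient, function(d)
    c(d, rep("", 5L))[1:5], character(5)))

  base_time <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  total_cases <- sum(n_cases)
  case_pat <- rep(seq_len(n_pat), n_cases)
  case_ids <- sprintf("%s-C%05d-%d", config$site_id, case_pat,
                      sequence(n_cases))
  t0 <- base_time + stats::runif(total_cases, 0, 3 * 365) * 86400

  per_analyte <- vector("list", length(config$analytes))
  for (a in seq_along(config$analytes)) {
    model <- config$analytes[[a]]
    m <- draw_counts(config$measurements_per_case, total_cases)
    row_case <- rep(seq_len(total_cases), m)
    row_pat <- case_pat[row_case]
    within <- sequence(m)
    vals <- draw_component_values(model, comp[[a]][row_pat],
                                  patients$age_years[row_pat],
                                  patients$sex[row_pat])
    nr <- length(row_pat)
    dev <- if (!is.null(model$devices)) {
      k <- sample(nrow(model$devices), nr, replace = TRUE,
                  prob = model$devices$weight)
      model$devices[k, c("analyzer_id", "kit_id"), drop = FALSE]
    } else data.frame(analyzer_id = rep("", nr), kit_id = rep("", nr))
    per_analyte[[a]] <- data.frame(
      patient_id = patients$patient_id[row_pat], case_id = case_ids[row_case],
      site_id = config$site_id, loinc = model$loinc, value = vals,
      unit = model$unit,
      timestamp = format(t0[row_case] + (within - 1L) * 3600 +
                           stats::runif(nr, 0, 1800),
                         "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      age_years = patients$age_years[row_pat], sex = patients$sex[row_pat],
      dx1 = dx_mat[row_pat, 1], dx2 = dx_mat[row_pat, 2],
      dx3 = dx_mat[row_pat, 3], dx4 = dx_mat[row_pat, 4],
      dx5 = dx_mat[row_pat, 5],
      analyzer_id = dev$analyzer_id, kit_id = dev$kit_id,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, per_analyte)
  out <- out[order(out$patient_id, out$case_id, out$loinc, out$timestamp), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Generate a multi-site consortium dataset
#'
#' Runs [generate_site_dataset()] for each configuration with an
#' independent seeded stream per site. When `master_seed` is given, each
#' site's seed is derived from it by site index, so adding a site never
#' perturbs the existing ones.
#'
#' @param configs list of [site_config()] objects with distinct `site_id`s.
#' @param master_seed optional integer; overrides per-site seeds with
#'   `(master_seed + 7919 * index) mod 2^31 - 1`.
#' @return named list mapping `site_id` to a measurement data frame.
#' @export
generate_multisite <- function(configs, master_seed = NULL) {
  ids <- vapply(configs, `[[`, character(1), "site_id")
  if (anyDuplicated(ids))
    ri_error("duplicate_site", "site_ids must be distinct")
  out <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    if (!is.null(master_seed))
      cfg$seed <- as.integer((master_seed + 7919 * i) %% (2^31 - 1))
    out[[i]] <- generate_site_dataset(cfg)
  }
  stats::setNames(out, ids)
}

#' Read a site configuration from YAML or JSON
#'
#' The file mirrors the [site_config()]/[analyte_model()] argument
#' structure; `analytes` entries are converted to [analyte_model()]
#' objects, with any `devices` entry coerced to a data frame.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [site_config()].
#' @export
read_site_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  analytes <- lapply(obj$analytes, function(a) {
    if (!is.null(a$devices) && !is.data.frame(a$devices))
      a$devices <- do.call(rbind.data.frame,
                           c(a$devices, stringsAsFactors = FALSE))
    if (!is.null(a$physio$sex_offset))
      a$physio$sex_offset <- unlist(a$physio$sex_offset)
    do.call(analyte_model, a)
  })
  obj$analytes <- analytes
  if (!is.null(obj$sex_props)) obj$sex_props <- unlist(obj$sex_props)
  do.call(site_config, obj)
}
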