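# Build a measurement data frame from recycled field vectors.
mk_records <- function(n, loinc = "2075-0", value = 100, unit = "mmol/L",
                       age = 50, sex = "female", patient = NULL,
                       case = NULL, ts = NULL, site = "A",
                       dx1 = "", dx2 = "", dx3 = "", dx4 = "", dx5 = "",
                       analyzer = "", kit = "") {
  if (is.null(patient)) patient <- sprintf("P%03d", seq_len(n))
  if (is.null(case)) case <- sprintf("C%03d", seq_len(n))
  if (is.null(ts)) ts <- sprintf("2022-01-%02dT08:00:00", (seq_len(n) %% 28) + 1)
  data.frame(
    patient_id = rep_len(patient, n), case_id = rep_len(case, n),
    site_id = rep_len(site, n), loinc = rep_len(loinc, n),
    value = rep_len(value, n), unit = rep_len(unit, n),
    timestamp = rep_len(ts, n), age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    dx1 = rep_len(dx1, n), dx2 = rep_len(dx2, n), dx3 = rep_len(dx3, n),
    dx4 = rep_len(dx4, n), dx5 = rep_len(dx5, n),
    analyzer_id = rep_len(analyzer, n), kit_id = rep_len(kit, n),
    stringsAsFactors = FALSE
  )
}

# Single-analyte Gaussian site configuration used across tests.
gaussian_site <- function(n, mu = 100, sigma = 5, site = "A", seed = 1,
                          patho = list(), loinc = "2075-0") {
  site_config(
    site, n,
    age = list(dist = "uniform", min = 20, max = 80),
    sex_props = c(female = 0.5, male = 0.5),
    analytes = list(analyte_model(
      loinc, "mmol/L",
      physio = list(family = "gaussian", mu = mu, sigma = sigma),
      patho = patho)),
    seed = seed
  )
}
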