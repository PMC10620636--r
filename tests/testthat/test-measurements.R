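test_that("cleaning rejects negative values, invalid ICD codes and malformed rows with one primary reason", {
  recs <- rbind(
    mk_records(1, value = -1.0),                               # chloride, negative
    mk_records(1, value = 101.0, dx1 = "E11.9"),               # valid
    mk_records(1, value = 99.0, dx1 = "X99.ZZZZ"),             # impossible code
    mk_records(1, value = NA_real_),                           # missing value
    mk_records(1, value = -2.0, dx1 = "X99.ZZZZ")              # negative wins
  )
  out <- clean_measurements(recs)
  expect_equal(nrow(out$kept), 1L)
  expect_equal(out$kept$value, 101.0)
  expect_equal(out$rejected$reason,
               c("negative_value", "invalid_icd", "malformed", "negative_value"))
})

test_that("allow_negative and an explicit code list change the cleaning outcome", {
  recs <- rbind(
    mk_records(1, loinc = "11555-0", value = -3.2),   # base excess: negatives fine
    mk_records(1, value = 100, dx1 = "E11.9"),
    mk_records(1, value = 100, dx1 = "E12.9")         # syntactically fine
  )
  out <- clean_measurements(recs, allow_negative = "11555-0",
                            valid_icd = c("E11.9"))
  expect_equal(nrow(out$kept), 2L)
  expect_equal(out$rejected$reason, "invalid_icd")
})

test_that("cleaning is idempotent and never raises on bad values", {
  recs <- rbind(mk_records(5), mk_records(1, value = Inf),
                mk_records(1, sex = "banana"))
  once <- clean_measurements(recs)
  twice <- clean_measurements(once$kept)
  expect_identical(once$kept, twice$kept)
  expect_equal(nrow(twice$rejected), 0L)
})

test_that("first_per_case keeps the earliest measurement per case and analyte, stably on ties", {
  recs <- mk_records(2, case = "C1", value = c(99, 104),
                     ts = c("2022-03-01T08:00:00", "2022-03-01T14:00:00"))
  expect_equal(first_per_case(recs)$value, 99)

  two <- mk_records(2, case = c("C1", "C2"))
  expect_equal(nrow(first_per_case(two)), 2L)

  tie <- mk_records(2, case = "C1", value = c(7, 8),
                    ts = "2022-03-01T08:00:00")
  expect_equal(first_per_case(tie)$value, 7)

  dedup <- first_per_case(rbind(recs, two))
  expect_identical(first_per_case(dedup), dedup)
})

test_that("apply_query filters on age (closed interval), sex, ICD prefixes and devices", {
  recs <- mk_records(3, age = c(57, 61, 58), sex = c("female", "female", "male"),
                     value = c(1, 2, 3))
  q <- cohort_query("2075-0", 55, 60, sexes = "female")
  s <- apply_query(recs, q)
  expect_s3_class(s, "reference_sample")
  expect_equal(s$values, 1)

  # closed on both ends
  edge <- mk_records(2, age = c(55, 60))
  expect_equal(apply_query(edge, q)$n, 2L)

  # prefix semantics, both directions
  dx <- mk_records(1, dx1 = "E11.9")
  expect_equal(apply_query(dx, cohort_query("2075-0", icd_include = "E11"))$n, 1L)
  expect_equal(apply_query(dx, cohort_query("2075-0", icd_exclude = "E11"))$n, 0L)

  # empty sex set is a vacuous filter
  expect_equal(apply_query(recs, cohort_query("2075-0", sexes = character()))$n, 0L)

  # device exact match
  dev <- mk_records(2, analyzer = c("A1", "A2"))
  expect_equal(apply_query(dev, cohort_query("2075-0", analyzer_id = "A1"))$n, 1L)
})

test_that("unknown/other sex matches only when explicitly included", {
  recs <- mk_records(3, sex = c("female", "other", "unknown"))
  expect_equal(apply_query(recs, cohort_query("2075-0"))$n, 1L)
  expect_equal(
    apply_query(recs, cohort_query("2075-0", sexes = sex_levels()))$n, 3L)
})

test_that("query results shrink monotonically as filters tighten", {
  set.seed(42)
  cfg <- gaussian_site(400, patho = list(
    list(fraction = 0.2, shift = 20, icd_prefix = "E87", p_icd = 1)))
  recs <- generate_site_dataset(cfg)
  base <- apply_query(recs, cohort_query("2075-0", 20, 80,
                                         sexes = sex_levels()))
  tighter <- list(
    cohort_query("2075-0", 30, 70, sexes = sex_levels()),
    cohort_query("2075-0", 20, 80, sexes = "female"),
    cohort_query("2075-0", 20, 80, sexes = sex_levels(),
                 icd_exclude = "E87")
  )
  for (q in tighter)
    expect_lte(apply_query(recs, q)$n, base$n)
})

test_that("disjoint age strata partition the unstratified sample", {
  set.seed(7)
  recs <- generate_site_dataset(gaussian_site(300))
  all <- apply_query(recs, cohort_query("2075-0", 20, 80))
  strata <- list(c(20, 39), c(40, 59), c(60, 80))
  ns <- vapply(strata, function(ab)
    apply_query(recs, cohort_query("2075-0", ab[1], ab[2]))$n, integer(1))
  expect_equal(sum(ns), all$n)
})

test_that("measurement CSV round-trips and load-time validation works", {
  set.seed(11)
  recs <- generate_site_dataset(gaussian_site(100))
  attr(recs, "truth") <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(recs, path)
  back <- read_measurements(path)
  expect_equal(back, recs)

  # missing column
  broken <- recs[, setdiff(names(recs), "loinc")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_measurements(p2), "missing_column: loinc",
               class = "rilab_missing_column")

  # malformed numeric row is dropped with a message, others load
  txt <- readLines(path)
  txt[2] <- sub("^([^,]*,[^,]*,[^,]*,[^,]*,)[^,]*", "\\1abc", txt[2])
  writeLines(txt, p2)
  expect_message(got <- read_measurements(p2), "malformed")
  expect_equal(nrow(got), nrow(recs) - 1L)

  # two units for one LOINC is a load-time error
  mixed <- rbind(mk_records(1, unit = "mmol/L"), mk_records(1, unit = "mg/dL"))
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(mixed, p3, row.names = FALSE)
  expect_error(read_measurements(p3), class = "rilab_unit_mismatch")
})
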