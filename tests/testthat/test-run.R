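make_run_fixture <- function(n = 400, seed = 77, patho = list()) {
  cfg <- gaussian_site(n, mu = 101, sigma = 3, seed = seed, patho = patho)
  d <- generate_site_dataset(cfg)
  path <- tempfile(fileext = ".csv")
  write_measurements(d, path)
  path
}

test_that("run_estimate executes the audited pooled pipeline and writes JSON", {
  csv <- make_run_fixture()
  out <- tempfile(fileext = ".json")
  config <- list(
    inputs = csv,
    query = list(loinc = "2075-0", age_min = 20, age_max = 80,
                 sexes = c("female", "male")),
    method = "nonparametric",
    settings = list(bootstrap_B = 100),
    seed = 5,
    output = out
  )
  msgs <- capture_messages(result <- run_estimate(config))
  expect_s3_class(result, "reference_interval")
  expect_true(any(grepl("query matched", msgs)))
  expect_true(file.exists(out))
  obj <- jsonlite::fromJSON(readLines(out))
  expect_equal(obj$method, "nonparametric")
  expect_equal(obj$n_used, result$n_used)
  expect_length(obj$ci_lower, 2L)
  file.remove(csv, out)
})

test_that("identical config and seed give byte-identical result files", {
  csv <- make_run_fixture(seed = 78)
  config <- list(inputs = csv,
                 query = list(loinc = "2075-0"),
                 settings = list(bootstrap_B = 100),
                 seed = 11, output = tempfile(fileext = ".json"))
  suppressMessages(run_estimate(config))
  first <- readLines(config$output)
  suppressMessages(run_estimate(config))
  expect_identical(readLines(config$output), first)
  file.remove(csv, config$output)
})

test_that("a query matching too few patients yields a typed refusal result", {
  csv <- make_run_fixture(n = 200, seed = 79)
  config <- list(inputs = csv,
                 query = list(loinc = "2075-0", age_min = 20, age_max = 23),
                 seed = 1)
  suppressMessages(result <- run_estimate(config))
  expect_true(is_refused(result))
  expect_lt(result$n, 120)
  file.remove(csv)
})

test_that("federated mode runs from per-site input files", {
  csvs <- c(A = make_run_fixture(n = 300, seed = 80),
            B = make_run_fixture(n = 300, seed = 81))
  config <- list(inputs = as.list(csvs), mode = "federated",
                 query = list(loinc = "2075-0", age_min = 20, age_max = 80),
                 settings = list(bootstrap_B = 50), seed = 9)
  suppressMessages(result <- run_estimate(config))
  expect_s3_class(result, "reference_interval")
  expect_equal(result$mode, "federated")
  file.remove(csvs)
})

test_that("run configurations load from YAML and JSON", {
  csv <- make_run_fixture(n = 150, seed = 82)
  y <- tempfile(fileext = ".yaml")
  writeLines(c("inputs:", paste0("  - ", csv), "query:",
               "  loinc: \"2075-0\"", "seed: 3",
               "settings:", "  bootstrap_B: 50"), y)
  suppressMessages(r1 <- run_estimate(y))
  expect_s3_class(r1, "reference_interval")
  file.remove(csv, y)
})

test_that("the command-line wrapper distinguishes success, refusal and error by exit code", {
  script <- system.file("cli", "rilab.R", package = "rilab")
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))

  csv <- make_run_fixture(n = 400, seed = 83)
  cfgfile <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(inputs = csv,
         query = list(loinc = "2075-0", age_min = 20, age_max = 80),
         settings = list(bootstrap_B = 50)),
    cfgfile, auto_unbox = TRUE)
  ok <- suppressWarnings(system2(
    rscript, c(script, "estimate", "--config", cfgfile,
               "--seed", "4", "--out", out),
    env = env, stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(out))
  expect_null(attr(ok, "status"))        # exit 0

  # refusal: impossible age range
  jsonlite::write_json(
    list(inputs = csv, query = list(loinc = "2075-0", age_min = 20,
                                    age_max = 21)),
    cfgfile, auto_unbox = TRUE)
  r <- suppressWarnings(system2(
    rscript, c(script, "estimate", "--config", cfgfile, "--seed", "4"),
    env = env, stdout = TRUE, stderr = TRUE))
  expect_equal(attr(r, "status"), 2L)

  # error: nonexistent input
  jsonlite::write_json(list(inputs = "/nonexistent.csv",
                            query = list(loinc = "2075-0")),
                       cfgfile, auto_unbox = TRUE)
  e <- suppressWarnings(system2(
    rscript, c(script, "estimate", "--config", cfgfile),
    env = env, stdout = TRUE, stderr = TRUE))
  expect_equal(attr(e, "status"), 1L)
  file.remove(csv, cfgfile, out)
})
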