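test_that("bin widths come from the 1-2-5 ladder, rounding up", {
  s <- choose_bin_spec(0, 9.7, 30)      # raw 0.323 -> 0.5
  expect_equal(s$width, 0.5)
  expect_equal(s$low_edge, 0)
  expect_gte(s$low_edge + s$n_bins * s$width, 9.7)

  expect_equal(choose_bin_spec(0, 100, 50)$width, 2)
  expect_equal(choose_bin_spec(-4.2, 3.9, 50)$width, 0.2)
  expect_error(choose_bin_spec(5, 5, 50), class = "rilab_empty_range")
  expect_error(bin_spec(0.3, 0, 10), class = "rilab_invalid_bin_width")
})

test_that("frequency tables use half-open bins and clamp out-of-range values", {
  t1 <- build_frequency_table(c(0.1, 0.6, 1.2), bin_spec(0.5, 0, 3), "A")
  expect_equal(t1$counts, c(1L, 1L, 1L))
  expect_equal(t1$n_total, 3L)

  t2 <- build_frequency_table(2.0, bin_spec(1, 2, 1), "A")
  expect_equal(t2$counts, 1L)

  # a value exactly on an interior edge lands in the upper bin
  t3 <- build_frequency_table(0.5, bin_spec(0.5, 0, 2), "A")
  expect_equal(t3$counts, c(0L, 1L))

  t4 <- build_frequency_table(c(-5, 0.2, 99), bin_spec(0.5, 0, 2), "A")
  expect_equal(t4$n_clamped, 2L)
  expect_equal(t4$n_total, 3L)

  expect_error(build_frequency_table(numeric(0), bin_spec(1, 0, 5), "A"),
               class = "rilab_empty_site_sample")
})

test_that("obfuscation is seed-deterministic, vanishes at huge epsilon, and has the right noise scale", {
  spec <- bin_spec(1, 0, 1000)
  tab <- frequency_table(spec, rep(100L, 1000), "A")

  none <- obfuscate_counts(tab, epsilon = 1e6, seed = 1)
  expect_equal(none$counts, tab$counts)
  expect_true(none$obfuscated)

  a <- obfuscate_counts(tab, epsilon = 1.0, seed = 7)
  b <- obfuscate_counts(tab, epsilon = 1.0, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_equal(a$n_total, sum(a$counts))

  # mean |noise| of the two-sided geometric law: 2q/(1-q^2), q = exp(-eps)
  q <- exp(-1)
  expected <- 2 * q / (1 - q^2)
  observed <- mean(abs(a$counts - tab$counts))
  expect_lt(abs(observed / expected - 1), 0.2)
})

test_that("aggregation sums counts element-wise and refuses mismatched bin specs", {
  spec <- bin_spec(0.5, 0, 3)
  tA <- frequency_table(spec, c(1L, 2L, 3L), "A")
  tB <- frequency_table(spec, c(4L, 5L, 6L), "B")

  one <- aggregate_frequency_tables(list(tA))
  expect_equal(one$counts, tA$counts)

  agg <- aggregate_frequency_tables(list(tA, tB))
  expect_equal(agg$counts, c(5L, 7L, 9L))
  expect_equal(agg$site_id, "AGGREGATE")
  expect_equal(agg$n_total, 21L)

  tC <- frequency_table(bin_spec(1, 0, 3), c(1L, 1L, 1L), "C")
  expect_error(aggregate_frequency_tables(list(tA, tC)),
               class = "rilab_bin_spec_mismatch")
})

test_that("histogram quantiles interpolate cumulative counts", {
  spec <- bin_spec(1, 0, 10)
  tab <- frequency_table(spec, rep(10L, 10), "A")
  expect_equal(quantiles_from_histogram(tab, 0.025), 0.25)
  expect_equal(quantiles_from_histogram(tab, 0.975), 9.75)
  expect_equal(quantiles_from_histogram(tab, 0.5), 5)

  # monotone in p
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(quantiles_from_histogram(tab, p)) >= 0))

  # all mass in one bin
  one <- frequency_table(spec, c(0L, 0L, 0L, 120L, rep(0L, 6)), "A")
  q <- quantiles_from_histogram(one, c(0.025, 0.975))
  expect_true(all(q >= 3 & q <= 4))

  empty <- frequency_table(spec, rep(0L, 10), "A")
  expect_error(quantiles_from_histogram(empty, 0.5),
               class = "rilab_empty_histogram")
})

test_that("federated limits track pooled nonparametric limits within one bin width", {
  set.seed(2024)
  x <- rnorm(6000)
  for (rep in 1:3) {
    split_id <- sample(1:3, 6000, replace = TRUE)
    sites <- split(x, split_id)
    fed <- federated_estimate(sites,
                              estimator_settings(bootstrap_B = 50,
                                                 rng_seed = rep))
    pooled <- nonparametric_ri(x)
    w <- fed$diagnostics$bin_width
    expect_lt(abs(fed$lower - pooled$lower), w)
    expect_lt(abs(fed$upper - pooled$upper), w)
  }
})

test_that("table aggregation is invariant to how the data are partitioned", {
  set.seed(31)
  x <- rnorm(3000, 50, 6)
  spec <- choose_bin_spec(min(x), max(x), 50)
  agg_for <- function(k) {
    chunks <- split(x, rep_len(seq_len(k), length(x)))
    tabs <- lapply(seq_along(chunks), function(i)
      build_frequency_table(chunks[[i]], spec, paste0("s", i)))
    aggregate_frequency_tables(tabs)$counts
  }
  expect_identical(agg_for(1), agg_for(2))
  expect_identical(agg_for(1), agg_for(5))
})

test_that("the aggregate minimum-n gate counts patients across sites", {
  set.seed(5)
  a <- runif(59); b <- runif(59)
  s <- estimator_settings(bootstrap_B = 50, rng_seed = 1)
  r118 <- federated_estimate(list(A = a, B = b), s)
  expect_true(is_refused(r118))
  expect_equal(r118$n, 118L)
  expect_equal(r118$mode, "federated")

  r120 <- federated_estimate(list(A = c(a, 0.5), B = c(b, 0.5)), s)
  expect_s3_class(r120, "reference_interval")
  expect_equal(r120$mode, "federated")
})

test_that("a single site degenerates to the local histogram estimate", {
  set.seed(6)
  x <- rnorm(2000, 30, 3)
  s <- estimator_settings(bootstrap_B = 50, rng_seed = 2)
  fed <- federated_estimate(list(only = x), s)
  kept <- three_sigma_filter(x)$kept
  spec <- choose_bin_spec(min(kept), max(kept), s$target_bins)
  tab <- build_frequency_table(kept, spec, "only")
  direct <- quantiles_from_histogram(tab, c(0.025, 0.975))
  expect_equal(unname(coef(fed)), direct)
})

test_that("obfuscation at huge epsilon reproduces the unobfuscated limits exactly", {
  set.seed(7)
  sites <- split(runif(900, 10, 20), rep(1:3, 300))
  s <- estimator_settings(bootstrap_B = 50, rng_seed = 3)
  plain <- federated_estimate(sites, s)
  obf <- federated_estimate(sites, s, epsilon = 1e9)
  expect_equal(coef(plain), coef(obf))
  expect_identical(plain$diagnostics$frequency_table$counts,
                   obf$diagnostics$frequency_table$counts)
})

test_that("no raw value crosses the cross-site boundary", {
  # the aggregation-side interface accepts frequency tables only
  expect_error(federated_estimate_from_tables(list(rnorm(200))),
               class = "rilab_raw_data_at_boundary")
  # and a frequency table exposes only bin structure and counts
  tab <- build_frequency_table(rnorm(500), bin_spec(1, -5, 10), "A")
  expect_named(tab, c("bin_spec", "counts", "n_total", "site_id",
                      "obfuscated", "n_clamped"))
})

test_that("masked aggregation recovers the exact aggregate from uninformative shares", {
  set.seed(8)
  spec <- bin_spec(1, 0, 20)
  tabs <- lapply(1:3, function(i)
    build_frequency_table(runif(200, 0, 20), spec, paste0("s", i)))
  m <- masked_aggregation(tabs, seed = 4)
  expect_identical(m$aggregate$counts,
                   aggregate_frequency_tables(tabs)$counts)
  # an individual masked share is not a count vector
  expect_true(any(m$masked[[1]] < 0 | m$masked[[1]] != round(m$masked[[1]])))
})
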