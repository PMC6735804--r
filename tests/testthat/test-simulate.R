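test_that("the generator is deterministic under a seed", {
  a <- simulate_countries(10, seed = 42)
  b <- simulate_countries(10, seed = 42)
  expect_identical(a, b)
  d1 <- file.path(tempdir(), "sim-a"); d2 <- file.path(tempdir(), "sim-b")
  write_country_tables(a, d1); write_country_tables(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # a different seed gives a different dataset
  expect_false(identical(a, simulate_countries(10, seed = 43)))
  # and the caller's RNG stream is untouched
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(simulate_countries(3, seed = 99)); y <- runif(1)
  expect_identical(x, y)
})

test_that("generated profiles always validate cleanly", {
  ctry <- simulate_countries(130, seed = 42)
  expect_length(ctry, 130)
  violations <- unlist(lapply(ctry, validate_profile))
  expect_length(violations, 0)
  expect_length(unique(names(ctry)), 130)
})

test_that("forcing universal breastfeeding zeroes the attributable burden", {
  ctry <- simulate_countries(1, seed = 7, ranges = list(
    ebf_0_5m = c(1, 1), any_bf_6_23m = c(1, 1), ever_breastfed = c(1, 1),
    bf_at_6m = c(1, 1), lifetime_duration = c(1, 1)))
  res <- estimate_country(ctry[[1]])
  df <- as.data.frame(res)
  burden_cols <- grep("^(cases|deaths)_", names(df), value = TRUE)
  expect_true(all(df[, burden_cols] == 0))
  expect_equal(res$health_cost_total, 0)
  expect_equal(res$loss_total, 0)
})

test_that("range overrides are honoured and bounded draws stay plausible", {
  ctry <- simulate_countries(40, seed = 5,
                             ranges = list(gni_per_capita = c(900, 1000)))
  gni <- vapply(ctry, `[[`, numeric(1), "gni_per_capita")
  expect_true(all(gni >= 900 & gni <= 1000))
  expect_true(all(vapply(ctry, `[[`, character(1), "income_group") == "low"))
  deflt <- simulate_countries(40, seed = 5)
  ebf <- vapply(deflt, function(p) p$prevalence$band_0_5m[["exclusive"]],
                numeric(1))
  expect_true(all(ebf >= 0.10 & ebf <= 0.60))
  le <- vapply(deflt, `[[`, numeric(1), "life_expectancy")
  expect_true(all(le >= 50 & le <= 85))
})

test_that("every generated dataset runs end-to-end without errors", {
  ctry <- simulate_countries(12, seed = 31)
  fit <- nbf_estimate(ctry)
  expect_s3_class(fit, "nbf_estimate")
  expect_equal(nrow(fit$table), 12)
  expect_false(anyNA(fit$table$loss_total))
  expect_true(all(fit$table$loss_total >= 0))
})
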