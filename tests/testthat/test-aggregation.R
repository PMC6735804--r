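test_that("scenario constructor pins the published rate pairs", {
  expect_equal(unlist(nbf_scenario("default")[c("discount_rate", "gdp_growth")]),
               c(discount_rate = 0.03, gdp_growth = 0.03))
  expect_equal(unlist(nbf_scenario("conservative")[c("discount_rate", "gdp_growth")]),
               c(discount_rate = 0.05, gdp_growth = 0.015))
  expect_equal(unlist(nbf_scenario("optimistic")[c("discount_rate", "gdp_growth")]),
               c(discount_rate = 0.015, gdp_growth = 0.05))
  expect_error(nbf_scenario("custom"), "requires")
  sc <- nbf_scenario("custom", 0.07, 0.01)
  expect_equal(sc$discount_rate, 0.07)
})

test_that("aggregation sums only countries with available data", {
  ctry <- simulate_countries(6, seed = 3)
  # knock one component out of one country
  ctry[[2]]$unit_costs$t2dm_expenditure_per_case <- NA_real_
  results <- lapply(ctry, estimate_country)
  agg <- aggregate_results(results, by = "global")
  df <- do.call(rbind, lapply(results, as.data.frame))
  expect_equal(agg$cost_t2dm, sum(df$cost_t2dm, na.rm = TRUE))
  expect_equal(agg$n_cost_t2dm, 5)
  expect_equal(agg$n_cost_diarrhoea, 6)
  # the excluded country contributes nothing, not zero
  expect_gt(sum(df$cost_t2dm, na.rm = TRUE), 0)
  # %GNI over the included set's GNI only
  inc <- !is.na(df$loss_total)
  expect_equal(agg$pct_gni, sum(df$loss_total[inc]) / sum(df$gni_total[inc]))
  # empty group: zero rows rather than fabricated totals
  agg_r <- aggregate_results(results, by = "region")
  expect_true(all(agg_r$group %in% df$region))
})

test_that("regional aggregates recompose into the global aggregate", {
  ctry <- simulate_countries(25, seed = 9)
  results <- lapply(ctry, estimate_country)
  reg <- aggregate_results(results, by = "region")
  glob <- aggregate_results(results, by = "global")
  for (f in c("deaths_child", "deaths_maternal", "cost_health_total",
              "loss_total"))
    expect_equal(sum(reg[[f]], na.rm = TRUE), glob[[f]], tolerance = 1e-9)
  expect_equal(sum(reg$n_countries), glob$n_countries)
})

test_that("sensitivity reruns move only the discount/growth-dependent parts", {
  ctry <- simulate_countries(8, seed = 13)
  sens <- run_sensitivity(ctry, by = "region")
  g <- sens[sens$group == "global", ]
  expect_equal(nrow(g), 3)
  con <- g[g$scenario == "conservative", ]
  def <- g[g$scenario == "default", ]
  opt <- g[g$scenario == "optimistic", ]
  expect_lte(con$loss_total, def$loss_total)
  expect_lte(def$loss_total, opt$loss_total)
  # burden and health costs are scenario-invariant
  expect_equal(con$cost_health_total, opt$cost_health_total)
  # with both scenarios at g = r the mortality PV depends on span only
  s1 <- nbf_scenario("custom", 0.02, 0.02)
  s2 <- nbf_scenario("custom", 0.06, 0.06)
  sens2 <- run_sensitivity(ctry[1], scenarios = list(s1, s2), by = "region")
  gg <- sens2[sens2$group == "global", ]
  expect_equal(gg$loss_child_mortality[1], gg$loss_child_mortality[2],
               tolerance = 1e-9)
})

test_that("printed-row aggregation reproduces a published total row", {
  tabs <- load_paper_tables()
  s <- aggregate_printed_rows(tabs$mortality, "income")
  expect_equal(unname(s[["deaths_child"]]), 595379)
  s4 <- aggregate_printed_rows(tabs$economic_losses, "region")
  expect_equal(unname(s4[["loss_total_usd_b"]]), 341.33, tolerance = 1e-9)
  # the two groupings recompose the same totals (obesity column, both exact)
  expect_equal(aggregate_printed_rows(tabs$morbidity, "region")[["cases_obesity"]],
               aggregate_printed_rows(tabs$morbidity, "income")[["cases_obesity"]])
})
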