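test_that("present value matches its frozen examples", {
  # growth and discount cancel: 2 full years of base 1000
  expect_equal(present_value(earnings_stream(1000, 18, 20, 0.03, 0.03)), 2000)
  # explicit two-year discounting, frozen from the per-year oracle
  pv <- present_value(earnings_stream(1000, 1, 3, 0, 0.05))
  expect_equal(pv, 1000 / 1.05 + 1000 / 1.05^2, tolerance = 1e-12)
  expect_equal(round(pv, 2), 1859.41)
  expect_equal(present_value(earnings_stream(0, 18, 65)), 0)
  expect_warning(v <- present_value(earnings_stream(1000, 30, 20)), "start")
  expect_equal(v, 0)
})

test_that("with g = r present value is exactly base x scale x span", {
  set.seed(21)
  for (i in 1:30) {
    r <- runif(1, 0, 0.08)
    base <- runif(1, 100, 50000)
    start <- runif(1, 0, 60)
    end <- start + runif(1, 0, 47)
    scale <- runif(1, 0.2, 1)
    pv <- present_value(earnings_stream(base, start, end, r, r, scale))
    expect_equal(pv, base * scale * (end - start), tolerance = 1e-9)
  }
})

test_that("present value is monotone in discount, growth and span", {
  s <- function(g, r, end) earnings_stream(1000, 18, end, g, r)
  expect_lt(present_value(s(0.03, 0.05, 65)), present_value(s(0.03, 0.03, 65)))
  expect_gt(present_value(s(0.05, 0.03, 65)), present_value(s(0.03, 0.03, 65)))
  expect_gt(present_value(s(0.03, 0.04, 66)), present_value(s(0.03, 0.04, 65)))
})

test_that("fractional terminal years are pro-rated", {
  full <- present_value(earnings_stream(1000, 18, 21, 0.02, 0.05))
  part <- present_value(earnings_stream(1000, 18, 20.25, 0.02, 0.05))
  two <- present_value(earnings_stream(1000, 18, 20, 0.02, 0.05))
  expect_gt(part, two); expect_lt(part, full)
  expect_equal(part - two, 0.25 * 1000 * (1.02 / 1.05)^20, tolerance = 1e-9)
})

test_that("child mortality loss is deaths x per-person present value", {
  p <- test_profile(gni_per_capita = 2000, life_expectancy = 80)
  a <- nbf_assumptions()  # g = r = 3%: PV = 2000 x 47
  expect_equal(child_mortality_loss(10, p, a), 10 * 2000 * 47)
  expect_equal(child_mortality_loss(0, p, a), 0)
  # linearity
  expect_equal(child_mortality_loss(100, p, a),
               10 * child_mortality_loss(10, p, a))
  # life expectancy below working age
  p2 <- test_profile(life_expectancy = 15)
  expect_warning(v <- child_mortality_loss(10, p2, a), "working age")
  expect_equal(v, 0)
  # life expectancy truncates the stream
  p3 <- test_profile(gni_per_capita = 2000, life_expectancy = 40)
  expect_equal(child_mortality_loss(10, p3, a), 10 * 2000 * 22)
})

test_that("maternal mortality loss counts only remaining productive years", {
  a <- nbf_assumptions()  # g = r
  p <- test_profile(gni_per_capita = 1000, life_expectancy = 80)
  p$epidemiology$t2dm$mean_age_at_death <- 55
  burdens <- list(t2dm = fake_burden("t2dm", NA_real_, deaths = 10))
  # 10 deaths x 1000 x (65 - 55) years
  expect_equal(maternal_mortality_loss(burdens, p, a), 10 * 1000 * 10)
  # mean age at death past retirement: no loss
  p$epidemiology$t2dm$mean_age_at_death <- 70
  expect_equal(maternal_mortality_loss(burdens, p, a), 0)
  # zero deaths
  burdens0 <- list(t2dm = fake_burden("t2dm", NA_real_, deaths = 0))
  p$epidemiology$t2dm$mean_age_at_death <- 55
  expect_equal(maternal_mortality_loss(burdens0, p, a), 0)
  # missing mean age -> not computed
  p$epidemiology$t2dm$mean_age_at_death <- NA_real_
  expect_true(is.na(maternal_mortality_loss(burdens, p, a)))
})

test_that("cognitive loss applies the IQ deficit to the earnings stream", {
  p <- test_profile(gni_per_capita = 10000, life_expectancy = 20)
  a <- nbf_assumptions()  # g = r, stream 18-20 = 2 years
  expect_equal(cognitive_loss(1, p, a), 10000 * 2 * 2.62 * 0.01067,
               tolerance = 1e-12)
  expect_equal(round(cognitive_loss(1, p, a), 2), 559.11)
  a0 <- nbf_assumptions(iq_gain = 0)
  expect_equal(cognitive_loss(1000, p, a0), 0)
  # everyone breastfed per recommendation -> no exposed children
  q <- test_profile()
  q$prevalence$band_0_5m <- c(exclusive = 1, predominant = 0, partial = 0,
                              none = 0)
  expect_equal(cognitive_exposed(q, nbf_assumptions()), 0)
  expect_equal(cognitive_loss(0, p, a), 0)
})

test_that("the alternative cognitive exposure mode uses breastfeeding at 6 months", {
  p <- test_profile()  # births 100 000, EBF 0.4, bf_at_6m 0.5
  expect_equal(cognitive_exposed(p, nbf_assumptions()), 60000)
  expect_equal(cognitive_exposed(p, nbf_assumptions(
    cognitive_exposure_mode = "bf_at_6m")), 50000)
})

test_that("wage-share and LFPR toggles scale the streams", {
  p <- test_profile(gni_per_capita = 1000, life_expectancy = 80)  # ws 0.5
  a_off <- nbf_assumptions()
  a_on <- nbf_assumptions(apply_wage_share = TRUE, apply_lfpr = TRUE)
  expect_equal(child_mortality_loss(10, p, a_on),
               0.5 * child_mortality_loss(10, p, a_off))
  p$epidemiology$t2dm$mean_age_at_death <- 55
  burdens <- list(t2dm = fake_burden("t2dm", NA_real_, deaths = 10))
  expect_equal(maternal_mortality_loss(burdens, p, a_on),
               0.5 * 0.5 * maternal_mortality_loss(burdens, p, a_off))
})

test_that("country totals sum the available components exactly", {
  p <- test_profile()
  res <- estimate_country(p)
  expect_equal(res$loss_total,
               res$health_cost_total + res$loss_child_mortality +
                 res$loss_maternal_mortality + res$loss_cognitive,
               tolerance = 1e-9)
  expect_equal(res$loss_total_pct_gni, res$loss_total / p$gni_total)
  expect_length(res$missing, 0)
  # a missing component is excluded from the total and recorded
  q <- test_profile()
  q$unit_costs$t2dm_expenditure_per_case <- NA_real_
  q$epidemiology$diarrhoea$incidence <- NA_real_
  res2 <- estimate_country(q)
  expect_false("health_system" %in% res2$missing)  # pneumonia still computed
  expect_true(is.na(res2$health_cost["diarrhoea"]))
  expect_true(is.na(res2$health_cost["t2dm"]))
})
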