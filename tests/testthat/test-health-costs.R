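test_that("the treatment cascade reproduces the hand-computed example", {
  p <- test_profile()
  tc <- child_treatment_cost(fake_burden("diarrhoea", 1000),
                             p$cascade$diarrhoea, p$unit_costs)
  # 1000 cases, 60% seek care, 10% inpatient;
  # outpatient 540 x 1 visit x (0.7*$5 + 0.3*$10) = $3510
  # inpatient 60 x 2 days x $20 = $2400
  expect_equal(tc$outpatient_cost, 3510)
  expect_equal(tc$inpatient_cost, 2400)
  expect_equal(tc$total_cost, 5910)
})

test_that("the cascade conserves cases and separates cases from costs", {
  p <- test_profile()
  tc <- child_treatment_cost(fake_burden("diarrhoea", 1234),
                             p$cascade$diarrhoea, p$unit_costs)
  expect_equal(tc$outpatient_cases + tc$inpatient_cases,
               1234 * p$cascade$diarrhoea$pct_taken_to_facility)
  expect_equal(tc$total_cost, tc$outpatient_cost + tc$inpatient_cost)
  # no care sought -> zero cost
  cs <- p$cascade$diarrhoea; cs$pct_taken_to_facility <- 0
  expect_equal(child_treatment_cost(fake_burden("diarrhoea", 1000), cs,
                                    p$unit_costs)$total_cost, 0)
  # zero unit costs -> zero cost but unchanged case counts
  uc <- p$unit_costs
  uc$outpatient_visit_cost[] <- 0; uc$inpatient_day_cost[] <- 0
  tc0 <- child_treatment_cost(fake_burden("diarrhoea", 1000),
                              p$cascade$diarrhoea, uc)
  expect_equal(tc0$total_cost, 0)
  expect_equal(tc0$outpatient_cases, 540)
})

test_that("cost is linear in cases and in unit costs", {
  p <- test_profile()
  t1 <- child_treatment_cost(fake_burden("pneumonia", 500),
                             p$cascade$pneumonia, p$unit_costs)
  t2 <- child_treatment_cost(fake_burden("pneumonia", 1500),
                             p$cascade$pneumonia, p$unit_costs)
  expect_equal(t2$total_cost, 3 * t1$total_cost, tolerance = 1e-12)
  uc <- p$unit_costs
  uc$outpatient_visit_cost <- 2 * uc$outpatient_visit_cost
  uc$inpatient_day_cost <- 2 * uc$inpatient_day_cost
  t3 <- child_treatment_cost(fake_burden("pneumonia", 500),
                             p$cascade$pneumonia, uc)
  expect_equal(t3$total_cost, 2 * t1$total_cost, tolerance = 1e-12)
})

test_that("a unit cost missing where the mix uses it blocks computation", {
  p <- test_profile()
  uc <- p$unit_costs
  uc$outpatient_visit_cost[["health_centre"]] <- NA  # mix weight 0.7 there
  tc <- child_treatment_cost(fake_burden("diarrhoea", 100),
                             p$cascade$diarrhoea, uc)
  expect_false(tc$computed)
  # but missing at an unused level is harmless
  uc2 <- p$unit_costs
  uc2$inpatient_day_cost[["tertiary_hospital"]] <- NA  # mix weight 0 there
  expect_true(child_treatment_cost(fake_burden("diarrhoea", 100),
                                   p$cascade$diarrhoea, uc2)$computed)
})

test_that("CPI inflation scales unit costs multiplicatively", {
  expect_equal(inflate_unit_cost(10, 1.35), 13.5)
  expect_equal(inflate_unit_cost(10, 1), 10)
  expect_equal(inflate_unit_cost(0, 2), 0)
  expect_error(inflate_unit_cost(10, 0), "positive")
  expect_error(inflate_unit_cost(10, -1), "positive")
})

test_that("diabetes treatment cost is cases x diagnosed share x expenditure", {
  p <- test_profile()
  expect_equal(t2dm_treatment_cost(fake_burden("t2dm", 1000), p$unit_costs),
               1000 * 0.5 * 200)
  uc <- p$unit_costs; uc$pct_t2dm_diagnosed <- 0
  expect_equal(t2dm_treatment_cost(fake_burden("t2dm", 1000), uc), 0)
  expect_equal(t2dm_treatment_cost(fake_burden("t2dm", 0), p$unit_costs), 0)
})

test_that("formula share is container spend over 24 months of earnings", {
  p <- test_profile(mean_monthly_wage = 640)
  # 50 containers x $18.74 over $640/month for 24 months
  expect_equal(formula_cost_share(p$unit_costs, p), 937 / 15360,
               tolerance = 1e-12)
  # free formula -> zero share; doubling the wage halves the share
  uc <- p$unit_costs; uc$formula_price_per_900g <- 0
  expect_equal(formula_cost_share(uc, p), 0)
  p2 <- test_profile(mean_monthly_wage = 1280)
  expect_equal(formula_cost_share(p$unit_costs, p2),
               formula_cost_share(p$unit_costs, p) / 2, tolerance = 1e-12)
  # zero wage is undefined, not infinite
  p3 <- test_profile(mean_monthly_wage = 0)
  expect_true(is.na(formula_cost_share(p$unit_costs, p3)))
})
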