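test_that("paf matches its closed forms", {
  # all mass on the reference category: no excess risk
  expect_equal(paf(c(ref = 1, exp = 0), c(ref = 1, exp = 2)), 0)
  # everyone exposed at RR 2: half the burden attributable
  expect_equal(paf(c(exposed = 1, ref = 0), c(exposed = 2, ref = 1)), 0.5)
  # three categories, frozen against the expected-risk-ratio oracle
  p <- c(a = 0.2, b = 0.3, c = 0.5)
  rr <- c(a = 1, b = 1.5, c = 2.5)
  expect_equal(paf(p, rr), 0.9 / 1.9, tolerance = 1e-12)
  expect_equal(paf(p, rr), oracle_paf(p, rr), tolerance = 1e-12)
})

test_that("paf rejects structural and validation breaches", {
  expect_error(paf(c(a = 0.5, b = 0.5), c(a = 1, x = 2)), "categories")
  expect_error(paf(c(a = 0.5, b = 0.4), c(a = 1, b = 2)), "sum to 1")
  expect_error(paf(c(a = 0.5, b = 0.5), c(a = 1.1, b = 2)), "reference")
})

test_that("paf is monotone in RR and in exposure shift", {
  set.seed(11)
  for (i in 1:50) {
    p <- as.vector(stats::rgamma(3, 1)); p <- p / sum(p)
    names(p) <- c("ref", "x", "y")
    rr <- c(ref = 1, x = runif(1, 1, 3), y = runif(1, 1, 3))
    f0 <- paf(p, rr)
    rr_up <- rr + c(0, 0.5, 0)
    expect_gte(paf(p, rr_up), f0)
    # move mass from reference to exposed
    shift <- min(p[["ref"]], 0.1)
    p2 <- p + c(-shift, shift, 0)
    expect_gte(paf(p2, rr), f0)
    expect_gte(f0, 0); expect_lt(f0, 1)
  }
})

test_that("acute child burden pools band PAFs by burden share", {
  p <- test_profile()
  # even split, band PAFs 0.5 and 0.25 -> 37.5% of 100 000 cases
  p$prevalence$band_0_5m <- c(exclusive = 0, predominant = 0, partial = 0,
                              none = 1)
  p$rr$diarrhoea$band_0_5m <- c(exclusive = 1, predominant = 1, partial = 1,
                                none = 2)       # PAF 0.5
  p$prevalence$band_6_23m <- c(any = 0, none = 1)
  p$rr$diarrhoea$band_6_23m <- c(any = 1, none = 4 / 3)  # PAF 0.25
  b <- child_pathway_burden(p, "diarrhoea")
  expect_equal(b$attributable_cases, 37500)
  # deaths all in the 0-5 m band with band PAF 0.4
  p$rr$diarrhoea$band_0_5m["none"] <- 5 / 3     # PAF 0.4
  p$epidemiology$diarrhoea$share_deaths_0_5m <- 1
  b <- child_pathway_burden(p, "diarrhoea")
  expect_equal(b$attributable_deaths, 400)
  # zero PAF in both bands -> zero burden
  q <- test_profile()
  q$prevalence$band_0_5m <- c(exclusive = 1, predominant = 0, partial = 0,
                              none = 0)
  q$prevalence$band_6_23m <- c(any = 1, none = 0)
  b0 <- child_pathway_burden(q, "pneumonia")
  expect_equal(b0$attributable_cases, 0)
  expect_equal(b0$attributable_deaths, 0)
})

test_that("attributable burden never exceeds observed burden", {
  set.seed(5)
  for (ct in simulate_countries(15, seed = 5)) {
    for (pw in c("diarrhoea", "pneumonia")) {
      b <- child_pathway_burden(ct, pw)
      expect_lte(b$attributable_cases, ct$epidemiology[[pw]]$incidence)
      expect_lte(b$attributable_deaths, ct$epidemiology[[pw]]$deaths)
      expect_gte(b$attributable_cases, 0)
    }
  }
})

test_that("obesity burden follows the two-category Levin form", {
  p <- test_profile()
  p$prevalence$ever_breastfed <- 0.5
  b <- obesity_burden(p)
  expect_equal(b$attributable_cases, 10000 * (1.2 - 1) / 1.2,
               tolerance = 1e-12)
  expect_true(is.na(b$attributable_deaths))
  # everyone ever breastfed: nothing attributable
  p$prevalence$ever_breastfed <- 1
  expect_equal(obesity_burden(p)$attributable_cases, 0)
  # null effect
  q <- test_profile()
  q$rr$obesity <- c(ever = 1, never = 1)
  expect_equal(obesity_burden(q)$attributable_cases, 0)
})

test_that("maternal burden applies the morbidity PAF to deaths unchanged", {
  p <- test_profile()
  p$prevalence$lifetime_duration_level <- 0.4   # p_exposed 0.6, RR 1.3
  b <- maternal_pathway_burden(p, "ovarian_cancer")
  expect_equal(b$attributable_deaths, 500 * 0.18 / 1.18, tolerance = 1e-9)
  expect_equal(b$paf_used[["cases"]], b$paf_used[["deaths"]])
  # counterfactual already met
  p$prevalence$lifetime_duration_level <- 1
  expect_equal(maternal_pathway_burden(p, "t2dm")$attributable_cases, 0)
  # null RR
  q <- test_profile()
  q$rr$breast_cancer <- c(recommended = 1, below = 1)
  expect_equal(maternal_pathway_burden(q, "breast_cancer")$attributable_deaths, 0)
})

test_that("literal maternal mode reproduces the prose product for audit", {
  p <- test_profile()  # level 0.4, t2dm RR 1.3, incidence 20 000
  b <- maternal_pathway_burden(p, "t2dm", mode = "literal")
  expect_equal(b$attributable_cases, 20000 * 0.3 * 0.6, tolerance = 1e-12)
})

test_that("missing epidemiology yields a not-computed marker, not zero", {
  p <- test_profile()
  p$epidemiology$diarrhoea$incidence <- NA_real_
  b <- child_pathway_burden(p, "diarrhoea")
  expect_false(b$computed)
  expect_true(is.na(b$attributable_cases))
  expect_match(b$reason, "not available")
})
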