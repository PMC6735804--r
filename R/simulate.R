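# Seeded synthetic country datasets.
#
# The generator emulates the shapes and plausible ranges of the open-access
# sources a real run would ingest (UN WPP demography, UNICEF IYCF
# breastfeeding prevalence, GBD incidence/mortality, MICS care seeking, WDI
# macro indicators, ILOSTAT labour indicators, WHO-CHOICE unit costs). The
# relative-risk ranges are configuration placeholders inside
# published-literature bounds, not any specific study's estimates.

sim_defaults <- list(
  population = c(1e6, 2e8),            # log-uniform
  crude_birth_rate = c(0.008, 0.045),
  gni_per_capita = c(500, 60000),      # log-uniform, US$
  wage_share = c(0.30, 0.65),
  lfpr_female = c(0.20, 0.80),
  cpi_multiplier = c(1.05, 1.90),
  ebf_0_5m = c(0.10, 0.60),
  any_bf_6_23m = c(0.30, 0.90),
  ever_breastfed = c(0.60, 0.99),
  bf_at_6m = c(0.30, 0.90),
  lifetime_duration = c(0.10, 0.60),
  diarrhoea_episodes_per_child = c(0.5, 3),
  diarrhoea_cfr = c(5e-4, 5e-3),
  pneumonia_episodes_per_child = c(0.02, 0.30),
  pneumonia_cfr = c(0.005, 0.05),
  obesity_incidence_per_child = c(0.002, 0.02),
  breast_cancer_mort_rate = c(1e-5, 2e-4),   # per total population
  ovarian_cancer_mort_rate = c(3e-6, 8e-5),
  t2dm_incidence_rate = c(1e-4, 2e-3),
  t2dm_mort_rate = c(1e-5, 2e-4),
  maternal_mean_age_death = c(55, 75),
  rr_diarrhoea_none_0_5m = c(2.0, 3.0),
  rr_diarrhoea_none_6_23m = c(1.3, 2.2),
  rr_pneumonia_none_0_5m = c(1.5, 2.5),
  rr_pneumonia_none_6_23m = c(1.2, 1.8),
  rr_obesity_never = c(1.2, 1.4),
  rr_breast_cancer = c(1.1, 1.3),
  rr_ovarian_cancer = c(1.2, 1.4),
  rr_t2dm = c(1.2, 1.5),
  pct_care_seeking = c(0.30, 0.90),
  pct_inpatient = c(0.05, 0.25),
  bed_days = c(2, 5),
  outpatient_cost_share_gni = c(0.001, 0.004), # health-centre visit / GNI pc
  t2dm_cost_share_gni = c(0.02, 0.15),
  pct_t2dm_diagnosed = c(0.30, 0.80),
  formula_price = c(12, 30),
  formula_containers = c(45, 75),
  prob_has_formula_price = c(0.75, 0.75))

runifr <- function(r) stats::runif(1, r[1], r[2])
rlogunif <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
rsimplex <- function(n) { x <- stats::rgamma(n, 1.5); x / sum(x) }

# World Bank-style income classification from GNI per capita (US$, Atlas-ish
# thresholds).
income_from_gni <- function(gni_pc) {
  if (gni_pc < 1086) "low"
  else if (gni_pc < 4256) "lower_middle"
  else if (gni_pc < 13206) "upper_middle"
  else "high"
}

iso3ish <- function(i) {
  a <- (i - 1) %/% 26L
  b <- (i - 1) %% 26L
  paste0("X", LETTERS[a + 1L], LETTERS[b + 1L])
}

#' Generate synthetic country profiles
#'
#' Draws a complete, internally consistent dataset of \code{n} country
#' profiles from fixed plausible indicator ranges. Identical seeds give
#' identical datasets, and every generated profile passes
#' \code{\link{validate_profile}} with zero violations. Countries lacking an
#' own formula price (a seeded draw) receive the generated global mean price
#' as proxy, mirroring the fallback the estimator assumes.
#'
#' @param n number of countries (>= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param ranges named list of \code{c(min, max)} overrides for any entry of
#'   the default range set (see the package source for names); forcing a
#'   degenerate range like \code{c(1, 1)} pins an indicator.
#' @return list of \code{nbf_profile}.
#' @examples
#' ctry <- simulate_countries(5, seed = 42)
#' validate_profile(ctry[[1]])
#' @export
simulate_countries <- function(n, seed = 1L, ranges = list()) {
  stopifnot(n >= 1)
  r <- utils::modifyList(sim_defaults, ranges)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    pop <- rlogunif(r$population)
    cbr <- runifr(r$crude_birth_rate)
    births <- pop * cbr
    children <- births * 2 * stats::runif(1, 0.94, 0.99)
    gni_pc <- rlogunif(r$gni_per_capita)
    le <- min(85, max(50, 48 + 5.5 * log10(gni_pc) + stats::rnorm(1, 0, 2)))
    region <- sample(nbf_regions, 1)

    ebf <- runifr(r$ebf_0_5m)
    rest <- rsimplex(3) * (1 - ebf)
    band05 <- c(exclusive = ebf, predominant = rest[1], partial = rest[2],
                none = rest[3])
    band05 <- band05 / sum(band05)
    anybf <- runifr(r$any_bf_6_23m)
    band623 <- c(any = anybf, none = 1 - anybf)

    prev <- nbf_prevalence(
      band_0_5m = band05, band_6_23m = band623,
      ever_breastfed = runifr(r$ever_breastfed),
      bf_at_6m = runifr(r$bf_at_6m),
      lifetime_duration_level = runifr(r$lifetime_duration))

    di_inc <- children * runifr(r$diarrhoea_episodes_per_child)
    pn_inc <- children * runifr(r$pneumonia_episodes_per_child)
    epi <- nbf_epidemiology(
      diarrhoea = list(incidence = di_inc,
                       deaths = di_inc * runifr(r$diarrhoea_cfr),
                       share_cases_0_5m = stats::runif(1, 0.3, 0.7),
                       share_deaths_0_5m = stats::runif(1, 0.3, 0.7)),
      pneumonia = list(incidence = pn_inc,
                       deaths = pn_inc * runifr(r$pneumonia_cfr),
                       share_cases_0_5m = stats::runif(1, 0.3, 0.7),
                       share_deaths_0_5m = stats::runif(1, 0.3, 0.7)),
      obesity = list(incidence = children * runifr(r$obesity_incidence_per_child)),
      breast_cancer = list(
        deaths = pop * runifr(r$breast_cancer_mort_rate),
        incidence = pop * runifr(r$breast_cancer_mort_rate) * stats::runif(1, 3, 8),
        mean_age_at_death = runifr(r$maternal_mean_age_death)),
      ovarian_cancer = list(
        deaths = pop * runifr(r$ovarian_cancer_mort_rate),
        incidence = pop * runifr(r$ovarian_cancer_mort_rate) * stats::runif(1, 3, 8),
        mean_age_at_death = runifr(r$maternal_mean_age_death)),
      t2dm = list(
        incidence = pop * runifr(r$t2dm_incidence_rate),
        deaths = pop * runifr(r$t2dm_mort_rate),
        mean_age_at_death = runifr(r$maternal_mean_age_death)))

    # RR gradients across 0-5m categories interpolate reference -> none
    rr_band05 <- function(rr_none) {
      c(exclusive = 1,
        predominant = 1 + 0.35 * (rr_none - 1),
        partial = 1 + 0.70 * (rr_none - 1),
        none = rr_none)
    }
    rr <- nbf_rr_table(
      diarrhoea = list(
        band_0_5m = rr_band05(runifr(r$rr_diarrhoea_none_0_5m)),
        band_6_23m = c(any = 1, none = runifr(r$rr_diarrhoea_none_6_23m))),
      pneumonia = list(
        band_0_5m = rr_band05(runifr(r$rr_pneumonia_none_0_5m)),
        band_6_23m = c(any = 1, none = runifr(r$rr_pneumonia_none_6_23m))),
      obesity = c(ever = 1, never = runifr(r$rr_obesity_never)),
      breast_cancer = c(recommended = 1, below = runifr(r$rr_breast_cancer)),
      ovarian_cancer = c(recommended = 1, below = runifr(r$rr_ovarian_cancer)),
      t2dm = c(recommended = 1, below = runifr(r$rr_t2dm)))

    casc1 <- function() list(
      pct_taken_to_facility = runifr(r$pct_care_seeking),
      pct_inpatient_given_care = runifr(r$pct_inpatient),
      facility_mix_outpatient = stats::setNames(rsimplex(4), nbf_facility_levels),
      facility_mix_inpatient = stats::setNames(rsimplex(4), nbf_facility_levels),
      visits_per_outpatient_case = sample(1:2, 1),
      bed_days_per_inpatient_case = runifr(r$bed_days))
    cascade <- nbf_cascade(diarrhoea = casc1(), pneumonia = casc1())

    hc_visit <- gni_pc * runifr(r$outpatient_cost_share_gni)
    level_mult <- c(1, 1.5, 2.2, 3) * stats::runif(4, 0.9, 1.1)
    out_cost <- stats::setNames(hc_visit * level_mult, nbf_facility_levels)
    in_cost <- out_cost * stats::runif(4, 2, 4)
    has_price <- stats::runif(1) < r$prob_has_formula_price[1]
    unit_costs <- nbf_unit_costs(
      outpatient_visit_cost = out_cost, inpatient_day_cost = in_cost,
      t2dm_expenditure_per_case = gni_pc * runifr(r$t2dm_cost_share_gni),
      pct_t2dm_diagnosed = runifr(r$pct_t2dm_diagnosed),
      formula_price_per_900g = if (has_price) runifr(r$formula_price) else NA,
      formula_containers_birth_to_24m = runifr(r$formula_containers))

    profiles[[i]] <- nbf_profile(
      country_code = iso3ish(i), region = region,
      income_group = income_from_gni(gni_pc),
      births_annual = births, children_0_23m = children, population = pop,
      gni_total = pop * gni_pc, gni_per_capita = gni_pc,
      life_expectancy = le, retirement_age = 65,
      wage_share = runifr(r$wage_share), lfpr_female = runifr(r$lfpr_female),
      mean_monthly_wage = gni_pc / 12 * stats::runif(1, 0.6, 1.4),
      cpi_cumulative_2008_2017 = runifr(r$cpi_multiplier),
      prevalence = prev, epidemiology = epi, rr = rr,
      cascade = cascade, unit_costs = unit_costs)
  }

  # global-mean proxy for countries without an own formula price
  prices <- vapply(profiles, function(p) p$unit_costs$formula_price_per_900g,
                   numeric(1))
  if (anyNA(prices) && any(!is.na(prices))) {
    proxy <- mean(prices, na.rm = TRUE)
    for (i in which(is.na(prices))) {
      profiles[[i]]$unit_costs$formula_price_per_900g <- proxy
      profiles[[i]]$data_flags <- profile_data_flags(profiles[[i]])
    }
  }
  names(profiles) <- vapply(profiles, `[[`, character(1), "country_code")
  profiles
}
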