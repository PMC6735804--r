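# Hand-built deterministic fixture country with round-number inputs, used by
# the unit tests. Built in code; nothing is read from disk.

test_profile <- function(...) {
  overrides <- list(...)
  p <- nbf_profile(
    country_code = "TST", region = "South Asia",
    income_group = "lower_middle",
    births_annual = 100000, children_0_23m = 200000, population = 5e6,
    gni_total = 5e9, gni_per_capita = 1000, life_expectancy = 70,
    retirement_age = 65, wage_share = 0.5, lfpr_female = 0.5,
    mean_monthly_wage = 100, cpi_cumulative_2008_2017 = 1,
    prevalence = nbf_prevalence(
      band_0_5m = c(exclusive = 0.4, predominant = 0.2, partial = 0.2,
                    none = 0.2),
      band_6_23m = c(any = 0.6, none = 0.4),
      ever_breastfed = 0.8, bf_at_6m = 0.5,
      lifetime_duration_level = 0.4),
    epidemiology = nbf_epidemiology(
      diarrhoea = list(incidence = 100000, deaths = 1000,
                       share_cases_0_5m = 0.5, share_deaths_0_5m = 0.5),
      pneumonia = list(incidence = 50000, deaths = 2000,
                       share_cases_0_5m = 0.5, share_deaths_0_5m = 0.5),
      obesity = list(incidence = 10000),
      breast_cancer = list(incidence = 8000, deaths = 2000,
                           mean_age_at_death = 60),
      ovarian_cancer = list(incidence = 1500, deaths = 500,
                            mean_age_at_death = 62),
      t2dm = list(incidence = 20000, deaths = 3000, mean_age_at_death = 58)),
    rr = nbf_rr_table(
      diarrhoea = list(
        band_0_5m = c(exclusive = 1, predominant = 1.5, partial = 2, none = 2.5),
        band_6_23m = c(any = 1, none = 1.5)),
      pneumonia = list(
        band_0_5m = c(exclusive = 1, predominant = 1.2, partial = 1.5, none = 2),
        band_6_23m = c(any = 1, none = 1.3)),
      obesity = c(ever = 1, never = 1.4),
      breast_cancer = c(recommended = 1, below = 1.2),
      ovarian_cancer = c(recommended = 1, below = 1.3),
      t2dm = c(recommended = 1, below = 1.3)),
    cascade = nbf_cascade(
      diarrhoea = list(
        pct_taken_to_facility = 0.6, pct_inpatient_given_care = 0.1,
        facility_mix_outpatient = c(health_centre = 0.7, primary_hospital = 0.3,
                                    secondary_hospital = 0, tertiary_hospital = 0),
        facility_mix_inpatient = c(health_centre = 0, primary_hospital = 0,
                                   secondary_hospital = 1, tertiary_hospital = 0),
        visits_per_outpatient_case = 1, bed_days_per_inpatient_case = 2),
      pneumonia = list(
        pct_taken_to_facility = 0.6, pct_inpatient_given_care = 0.1,
        facility_mix_outpatient = c(health_centre = 0.7, primary_hospital = 0.3,
                                    secondary_hospital = 0, tertiary_hospital = 0),
        facility_mix_inpatient = c(health_centre = 0, primary_hospital = 0,
                                   secondary_hospital = 1, tertiary_hospital = 0),
        visits_per_outpatient_case = 1, bed_days_per_inpatient_case = 2)),
    unit_costs = nbf_unit_costs(
      outpatient_visit_cost = c(health_centre = 5, primary_hospital = 10,
                                secondary_hospital = 15, tertiary_hospital = 20),
      inpatient_day_cost = c(health_centre = 10, primary_hospital = 20,
                             secondary_hospital = 20, tertiary_hospital = 40),
      t2dm_expenditure_per_case = 200, pct_t2dm_diagnosed = 0.5,
      formula_price_per_900g = 18.74, formula_containers_birth_to_24m = 50))
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  p$data_flags <- profile_data_flags(p)
  p
}

# burden stub with a given case/death count, for cost-side tests
fake_burden <- function(pathway, cases, deaths = NA_real_) {
  structure(list(pathway = pathway, attributable_cases = cases,
                 attributable_deaths = deaths,
                 paf_used = c(cases = NA_real_, deaths = NA_real_),
                 computed = TRUE, reason = NULL),
            class = "nbf_pathway_burden")
}

# independent brute-force PAF oracle: expected absolute risks under the
# current mix vs the all-reference counterfactual
oracle_paf <- function(p, rr, r0 = 0.07) {
  risk_now <- sum(p * (r0 * rr))
  (risk_now - r0) / risk_now
}

# independent per-year loop oracle for the earnings-stream present value
oracle_pv <- function(base, start, end, g, r, scale = 1) {
  if (start >= end) return(0)
  total <- 0
  for (a in 0:300) {
    lo <- max(a, start)
    hi <- min(a + 1, end)
    if (hi > lo)
      total <- total + (hi - lo) * base * scale * (1 + g)^a / (1 + r)^a
  }
  total
}
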