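# Domain types: country profile and its sub-records.
#
# All records are plain lists with a class attribute and a constructor that
# fixes field names and shapes. Numeric fields may be NA ("indicator not
# available"); availability is tracked explicitly in data_flags and propagates
# downstream as "component not computed", never as a silent zero.

#' Facility levels of the care-seeking cascade
#' @export
nbf_facility_levels <- c("health_centre", "primary_hospital",
                         "secondary_hospital", "tertiary_hospital")

#' World Bank regions used for aggregation
#' @export
nbf_regions <- c("East Asia and Pacific", "Europe and Central Asia",
                 "Middle East and North Africa", "Latin America and Caribbean",
                 "North America", "South Asia", "Sub-Saharan Africa")

#' Country income groups used for aggregation
#' @export
nbf_income_groups <- c("high", "upper_middle", "lower_middle", "low")

#' Disease pathways
#'
#' Child pathways: diarrhoea and pneumonia (ages 0--23 months, two exposure
#' age bands) and childhood obesity (ever/never breastfed). Maternal pathways:
#' breast cancer, ovarian cancer and type II diabetes in women, driven by the
#' population's attainment of recommended lifetime breastfeeding.
#' @export
nbf_pathways <- c("diarrhoea", "pneumonia", "obesity",
                  "breast_cancer", "ovarian_cancer", "t2dm")

num_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA_real_)
  as.numeric(x)
}

#' Breastfeeding-practice prevalence record
#'
#' @param band_0_5m named fractions over categories
#'   \code{exclusive, predominant, partial, none} for infants under 6 months;
#'   must sum to 1.
#' @param band_6_23m named fractions over \code{any, none} for ages 6--23
#'   months; must sum to 1.
#' @param ever_breastfed fraction of children ever breastfed.
#' @param bf_at_6m fraction of children still breastfed at 6 months.
#' @param lifetime_duration_level population mean attainment of recommended
#'   lifetime breastfeeding, in [0,1]; drives the maternal pathways.
#' @return object of class \code{nbf_prevalence}.
#' @export
nbf_prevalence <- function(band_0_5m, band_6_23m, ever_breastfed = NA,
                           bf_at_6m = NA, lifetime_duration_level = NA) {
  band_0_5m <- band_0_5m[c("exclusive", "predominant", "partial", "none")]
  band_6_23m <- band_6_23m[c("any", "none")]
  structure(list(band_0_5m = band_0_5m, band_6_23m = band_6_23m,
                 ever_breastfed = num_or_na(ever_breastfed),
                 bf_at_6m = num_or_na(bf_at_6m),
                 lifetime_duration_level = num_or_na(lifetime_duration_level)),
            class = "nbf_prevalence")
}

#' Disease epidemiology record
#'
#' One entry per pathway. Acute child pathways (diarrhoea, pneumonia) carry
#' annual incident cases and deaths for ages 0--23 months plus the share of
#' each falling in the 0--5 month band (the age-band pooling weights).
#' Maternal pathways carry incidence, deaths and the mean age at death of
#' women, from which foregone productive years are counted. Chronic-disease
#' deaths and incident cases are different cohorts, so deaths <= incidence is
#' deliberately not enforced.
#'
#' @param diarrhoea,pneumonia lists with elements \code{incidence},
#'   \code{deaths}, \code{share_cases_0_5m}, \code{share_deaths_0_5m}.
#' @param obesity list with element \code{incidence} (annual new cases of
#'   childhood obesity).
#' @param breast_cancer,ovarian_cancer,t2dm lists with elements
#'   \code{incidence}, \code{deaths}, \code{mean_age_at_death}.
#' @return object of class \code{nbf_epidemiology}.
#' @export
nbf_epidemiology <- function(diarrhoea = NULL, pneumonia = NULL,
                             obesity = NULL, breast_cancer = NULL,
                             ovarian_cancer = NULL, t2dm = NULL) {
  acute <- function(x) list(
    incidence = num_or_na(x$incidence), deaths = num_or_na(x$deaths),
    share_cases_0_5m = if (is.null(x$share_cases_0_5m)) 0.5 else as.numeric(x$share_cases_0_5m),
    share_deaths_0_5m = if (is.null(x$share_deaths_0_5m)) 0.5 else as.numeric(x$share_deaths_0_5m))
  maternal <- function(x) list(
    incidence = num_or_na(x$incidence), deaths = num_or_na(x$deaths),
    mean_age_at_death = num_or_na(x$mean_age_at_death))
  structure(list(
    diarrhoea = acute(diarrhoea), pneumonia = acute(pneumonia),
    obesity = list(incidence = num_or_na(obesity$incidence)),
    breast_cancer = maternal(breast_cancer),
    ovarian_cancer = maternal(ovarian_cancer),
    t2dm = maternal(t2dm)), class = "nbf_epidemiology")
}

#' Relative-risk table
#'
#' Per pathway, relative risk of disease by breastfeeding-exposure category,
#' with the recommended practice as the reference category (RR = 1).
#'
#' @param diarrhoea,pneumonia lists with named RR vectors \code{band_0_5m}
#'   (categories exclusive/predominant/partial/none) and \code{band_6_23m}
#'   (any/none).
#' @param obesity named RR vector over \code{ever, never} (ever breastfed is
#'   the reference).
#' @param breast_cancer,ovarian_cancer,t2dm named RR vectors over
#'   \code{recommended, below} (recommended lifetime breastfeeding is the
#'   reference).
#' @return object of class \code{nbf_rr_table}.
#' @export
nbf_rr_table <- function(diarrhoea, pneumonia, obesity,
                         breast_cancer, ovarian_cancer, t2dm) {
  structure(list(diarrhoea = diarrhoea, pneumonia = pneumonia,
                 obesity = obesity, breast_cancer = breast_cancer,
                 ovarian_cancer = ovarian_cancer, t2dm = t2dm),
            class = "nbf_rr_table")
}

#' Care-seeking cascade for the acute child pathways
#'
#' @param diarrhoea,pneumonia lists with elements
#'   \code{pct_taken_to_facility}, \code{pct_inpatient_given_care},
#'   \code{facility_mix_outpatient}, \code{facility_mix_inpatient} (named
#'   fractions over \code{nbf_facility_levels}, each summing to 1),
#'   \code{visits_per_outpatient_case} (default 1) and
#'   \code{bed_days_per_inpatient_case} (default 3).
#' @return object of class \code{nbf_cascade}.
#' @export
nbf_cascade <- function(diarrhoea, pneumonia) {
  fill <- function(x) {
    visits <- if (is.null(x$visits_per_outpatient_case) ||
                  is.na(x$visits_per_outpatient_case)) 1 else
      as.numeric(x$visits_per_outpatient_case)
    days <- if (is.null(x$bed_days_per_inpatient_case) ||
                is.na(x$bed_days_per_inpatient_case)) 3 else
      as.numeric(x$bed_days_per_inpatient_case)
    list(pct_taken_to_facility = num_or_na(x$pct_taken_to_facility),
         pct_inpatient_given_care = num_or_na(x$pct_inpatient_given_care),
         visits_per_outpatient_case = visits,
         bed_days_per_inpatient_case = days,
         facility_mix_outpatient = x$facility_mix_outpatient[nbf_facility_levels],
         facility_mix_inpatient = x$facility_mix_inpatient[nbf_facility_levels])
  }
  structure(list(diarrhoea = fill(diarrhoea), pneumonia = fill(pneumonia)),
            class = "nbf_cascade")
}

#' Unit costs record
#'
#' @param outpatient_visit_cost,inpatient_day_cost named US$ vectors over
#'   \code{nbf_facility_levels} (cost per outpatient visit / inpatient bed
#'   day). These are WHO-CHOICE-style unit costs and are the only costs the
#'   CPI multiplier is applied to.
#' @param t2dm_expenditure_per_case annual US$ health expenditure per
#'   diagnosed case of type II diabetes.
#' @param pct_t2dm_diagnosed fraction of type II diabetes cases diagnosed.
#' @param formula_price_per_900g US$ price of a 900-g container of the
#'   cheapest economy-brand infant formula.
#' @param formula_containers_birth_to_24m number of containers needed to feed
#'   a child formula from birth to age two.
#' @return object of class \code{nbf_unit_costs}.
#' @export
nbf_unit_costs <- function(outpatient_visit_cost, inpatient_day_cost,
                           t2dm_expenditure_per_case = NA,
                           pct_t2dm_diagnosed = NA,
                           formula_price_per_900g = NA,
                           formula_containers_birth_to_24m = NA) {
  structure(list(
    outpatient_visit_cost = outpatient_visit_cost[nbf_facility_levels],
    inpatient_day_cost = inpatient_day_cost[nbf_facility_levels],
    t2dm_expenditure_per_case = num_or_na(t2dm_expenditure_per_case),
    pct_t2dm_diagnosed = num_or_na(pct_t2dm_diagnosed),
    formula_price_per_900g = num_or_na(formula_price_per_900g),
    formula_containers_birth_to_24m = num_or_na(formula_containers_birth_to_24m)),
    class = "nbf_unit_costs")
}

#' Country profile
#'
#' The full input record for one country: demography, breastfeeding practice,
#' epidemiology, relative risks, care seeking, unit costs and macro-economic
#' indicators. Missing indicators are NA and flagged in \code{data_flags};
#' downstream components depending on them are reported as not computed.
#'
#' @param country_code ISO3 code.
#' @param region one of \code{nbf_regions}.
#' @param income_group one of \code{nbf_income_groups}.
#' @param births_annual live births in the reference year.
#' @param children_0_23m population aged 0--23 months.
#' @param population total population.
#' @param gni_total,gni_per_capita gross national income, US$ current.
#' @param life_expectancy years.
#' @param retirement_age years (default 65).
#' @param wage_share labour share of national income, fraction.
#' @param lfpr_female female labour-force participation rate, fraction.
#' @param mean_monthly_wage US$.
#' @param cpi_cumulative_2008_2017 cumulative CPI multiplier applied to
#'   WHO-CHOICE-era unit costs.
#' @param prevalence an \code{nbf_prevalence}.
#' @param epidemiology an \code{nbf_epidemiology}.
#' @param rr an \code{nbf_rr_table}.
#' @param cascade an \code{nbf_cascade}.
#' @param unit_costs an \code{nbf_unit_costs}.
#' @return object of class \code{nbf_profile}.
#' @export
nbf_profile <- function(country_code, region, income_group,
                        births_annual, children_0_23m, population,
                        gni_total, gni_per_capita, life_expectancy,
                        retirement_age = 65, wage_share = NA,
                        lfpr_female = NA, mean_monthly_wage = NA,
                        cpi_cumulative_2008_2017 = 1,
                        prevalence, epidemiology, rr, cascade, unit_costs) {
  p <- structure(list(
    country_code = as.character(country_code),
    region = as.character(region),
    income_group = as.character(income_group),
    births_annual = num_or_na(births_annual),
    children_0_23m = num_or_na(children_0_23m),
    population = num_or_na(population),
    gni_total = num_or_na(gni_total),
    gni_per_capita = num_or_na(gni_per_capita),
    life_expectancy = num_or_na(life_expectancy),
    retirement_age = num_or_na(retirement_age),
    wage_share = num_or_na(wage_share),
    lfpr_female = num_or_na(lfpr_female),
    mean_monthly_wage = num_or_na(mean_monthly_wage),
    cpi_cumulative_2008_2017 = num_or_na(cpi_cumulative_2008_2017),
    prevalence = prevalence, epidemiology = epidemiology,
    rr = rr, cascade = cascade, unit_costs = unit_costs),
    class = "nbf_profile")
  p$data_flags <- profile_data_flags(p)
  p
}

ok_num <- function(x) length(x) == 1L && !is.na(x)

#' Per-indicator availability flags for a profile
#'
#' @param profile an \code{nbf_profile}.
#' @return named logical vector; FALSE marks an indicator whose absence makes
#'   one or more result components not computable.
#' @export
profile_data_flags <- function(profile) {
  ep <- profile$epidemiology
  c(demography = ok_num(profile$births_annual) && ok_num(profile$children_0_23m),
    gni = ok_num(profile$gni_total) && ok_num(profile$gni_per_capita),
    life_expectancy = ok_num(profile$life_expectancy),
    wage = ok_num(profile$mean_monthly_wage),
    prevalence_0_5m = !anyNA(profile$prevalence$band_0_5m),
    prevalence_6_23m = !anyNA(profile$prevalence$band_6_23m),
    ever_breastfed = ok_num(profile$prevalence$ever_breastfed),
    bf_at_6m = ok_num(profile$prevalence$bf_at_6m),
    lifetime_duration = ok_num(profile$prevalence$lifetime_duration_level),
    epi_diarrhoea = ok_num(ep$diarrhoea$incidence) && ok_num(ep$diarrhoea$deaths),
    epi_pneumonia = ok_num(ep$pneumonia$incidence) && ok_num(ep$pneumonia$deaths),
    epi_obesity = ok_num(ep$obesity$incidence),
    epi_breast_cancer = ok_num(ep$breast_cancer$deaths),
    epi_ovarian_cancer = ok_num(ep$ovarian_cancer$deaths),
    epi_t2dm = ok_num(ep$t2dm$incidence),
    unit_costs = !anyNA(profile$unit_costs$outpatient_visit_cost) &&
      !anyNA(profile$unit_costs$inpatient_day_cost),
    t2dm_costs = ok_num(profile$unit_costs$t2dm_expenditure_per_case) &&
      ok_num(profile$unit_costs$pct_t2dm_diagnosed),
    formula_price = ok_num(profile$unit_costs$formula_price_per_900g))
}

frac_ok <- function(x) !is.na(x) & x >= 0 & x <= 1

#' Validate a country profile
#'
#' Checks every structural invariant of the profile and its sub-records and
#' returns the violations found. Validation never raises: a missing (NA)
#' indicator is not a violation (it is a flagged absence), but an
#' out-of-range or inconsistent value is.
#'
#' @param profile an \code{nbf_profile}.
#' @return character vector of violations, each naming the offending field
#'   path; empty when the profile is valid.
#' @export
validate_profile <- function(profile) {
  v <- character(0)
  bad <- function(path, msg) v <<- c(v, paste0(path, ": ", msg))

  if (!profile$region %in% nbf_regions)
    bad("region", paste("unknown region", profile$region))
  if (!profile$income_group %in% nbf_income_groups)
    bad("income_group", paste("unknown income group", profile$income_group))
  for (f in c("births_annual", "children_0_23m", "population", "gni_total",
              "gni_per_capita", "mean_monthly_wage"))
    if (ok_num(profile[[f]]) && profile[[f]] < 0) bad(f, "negative value")
  if (ok_num(profile$life_expectancy) && profile$life_expectancy <= 0)
    bad("life_expectancy", "must be > 0")
  if (ok_num(profile$cpi_cumulative_2008_2017) &&
      profile$cpi_cumulative_2008_2017 < 0)
    bad("cpi_cumulative_2008_2017", "must be >= 0")
  for (f in c("wage_share", "lfpr_female"))
    if (ok_num(profile[[f]]) && !frac_ok(profile[[f]]))
      bad(f, "fraction outside [0,1]")

  pv <- profile$prevalence
  check_simplex <- function(x, path) {
    if (anyNA(x)) return(invisible())
    if (any(!frac_ok(x))) bad(path, "fraction outside [0,1]")
    if (abs(sum(x) - 1) > 1e-9)
      bad(path, sprintf("category fractions sum to %.6f, not 1", sum(x)))
  }
  check_simplex(pv$band_0_5m, "prevalence.band_0_5m")
  check_simplex(pv$band_6_23m, "prevalence.band_6_23m")
  for (f in c("ever_breastfed", "bf_at_6m", "lifetime_duration_level"))
    if (ok_num(pv[[f]]) && !frac_ok(pv[[f]]))
      bad(paste0("prevalence.", f), "fraction outside [0,1]")

  for (pw in nbf_pathways) {
    e <- profile$epidemiology[[pw]]
    for (f in names(e))
      if (ok_num(e[[f]]) && e[[f]] < 0)
        bad(paste0("epidemiology.", pw, ".", f), "negative value")
    for (f in intersect(names(e), c("share_cases_0_5m", "share_deaths_0_5m")))
      if (ok_num(e[[f]]) && !frac_ok(e[[f]]))
        bad(paste0("epidemiology.", pw, ".", f), "fraction outside [0,1]")
    rr <- profile$rr[[pw]]
    rrvecs <- if (is.list(rr)) rr else list(rr)
    nm <- if (is.list(rr)) paste0(pw, ".", names(rr)) else pw
    for (i in seq_along(rrvecs)) {
      x <- rrvecs[[i]]
      if (anyNA(x)) next
      if (any(x <= 0)) bad(paste0("rr.", nm[i]), "RR must be > 0")
      if (!any(abs(x - 1) < 1e-12))
        bad(paste0("rr.", nm[i]), "no reference category with RR = 1")
    }
  }

  for (pw in c("diarrhoea", "pneumonia")) {
    cs <- profile$cascade[[pw]]
    for (f in c("pct_taken_to_facility", "pct_inpatient_given_care"))
      if (ok_num(cs[[f]]) && !frac_ok(cs[[f]]))
        bad(paste0("cascade.", pw, ".", f), "fraction outside [0,1]")
    for (f in c("facility_mix_outpatient", "facility_mix_inpatient"))
      check_simplex(cs[[f]], paste0("cascade.", pw, ".", f))
    for (f in c("visits_per_outpatient_case", "bed_days_per_inpatient_case"))
      if (ok_num(cs[[f]]) && cs[[f]] < 0)
        bad(paste0("cascade.", pw, ".", f), "negative value")
  }

  uc <- profile$unit_costs
  for (f in c("outpatient_visit_cost", "inpatient_day_cost"))
    if (!anyNA(uc[[f]]) && any(uc[[f]] < 0))
      bad(paste0("unit_costs.", f), "negative cost")
  for (f in c("t2dm_expenditure_per_case", "formula_price_per_900g",
              "formula_containers_birth_to_24m"))
    if (ok_num(uc[[f]]) && uc[[f]] < 0)
      bad(paste0("unit_costs.", f), "negative value")
  if (ok_num(uc$pct_t2dm_diagnosed) && !frac_ok(uc$pct_t2dm_diagnosed))
    bad("unit_costs.pct_t2dm_diagnosed", "fraction outside [0,1]")
  v
}

#' @export
print.nbf_profile <- function(x, ...) {
  cat(sprintf("<nbf_profile> %s  [%s, %s income]\n", x$country_code,
              x$region, gsub("_", "-", x$income_group)))
  cat(sprintf("  births/yr %s, GNI pc US$%s, life expectancy %.1f y\n",
              format(x$births_annual, big.mark = ","),
              format(x$gni_per_capita, big.mark = ","), x$life_expectancy))
  cat(sprintf("  EBF <6m: %.0f%%; indicators available: %d/%d\n",
              100 * x$prevalence$band_0_5m[["exclusive"]],
              sum(x$data_flags), length(x$data_flags)))
  invisible(x)
}
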