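# Human-capital economic losses: discounted future earnings streams.

#' Earnings stream specification
#'
#' An annual earnings stream over the age interval [start_age, end_age), with
#' end_age exclusive (the age at which earning stops: retirement or life
#' expectancy, whichever comes first). Earnings in the year lived at age a are
#' base_income x scale x (1+growth)^a, discounted to the cohort's reference
#' (birth) year by (1+discount)^a with annual end-of-year compounding.
#' Fractional start or end ages pro-rate the partial years.
#'
#' @param base_income US$/year at the reference year (GNI per capita proxy).
#' @param start_age,end_age years; \code{start_age <= end_age}.
#' @param growth annual growth rate of the income proxy.
#' @param discount annual discount rate.
#' @param scale product of optional multipliers (wage share, labour-force
#'   participation); default 1.
#' @return object of class \code{nbf_stream}.
#' @export
earnings_stream <- function(base_income, start_age, end_age,
                            growth = 0.03, discount = 0.03, scale = 1) {
  structure(list(base_income = base_income, start_age = start_age,
                 end_age = end_age, growth = growth, discount = discount,
                 scale = scale), class = "nbf_stream")
}

#' Present value of an earnings stream (per person)
#'
#' Sums base_income x scale x ((1+g)/(1+r))^a over the age-years covered by
#' the stream, pro-rating fractional first and last years. With g = r every
#' year contributes base x scale, so the value is exactly
#' base x scale x (end - start).
#'
#' @param stream an \code{nbf_stream}.
#' @return US$ present value per person; 0 (with a warning) when the stream
#'   is empty (\code{start_age >= end_age}).
#' @export
present_value <- function(stream) {
  s <- stream$start_age
  e <- stream$end_age
  if (is.na(s) || is.na(e) || is.na(stream$base_income)) return(NA_real_)
  if (s >= e) {
    if (s > e) warning("earnings stream has start_age > end_age; value 0")
    return(0)
  }
  ages <- seq.int(floor(s), ceiling(e) - 1L)
  weight <- pmin(ages + 1, e) - pmax(ages, s)  # overlap of [a, a+1) with [s, e)
  ratio <- (1 + stream$growth) / (1 + stream$discount)
  sum(weight * stream$base_income * stream$scale * ratio^ages)
}

# Common scale factor for earnings streams given the assumption toggles.
stream_scale <- function(profile, assumptions, maternal = FALSE) {
  sc <- 1
  if (assumptions$apply_wage_share && !is.na(profile$wage_share))
    sc <- sc * profile$wage_share
  if (maternal && assumptions$apply_lfpr && !is.na(profile$lfpr_female))
    sc <- sc * profile$lfpr_female
  sc
}

working_end_age <- function(profile, assumptions) {
  min(assumptions$retirement_age, profile$life_expectancy)
}

#' Future earnings lost to attributable child mortality
#'
#' Each child death forfeits the country's projected GNI per capita over the
#' productive years from \code{work_start_age} until the earlier of
#' retirement and life expectancy, discounted to the cohort's birth year.
#'
#' @param deaths attributable child deaths (one-year cohort).
#' @param profile an \code{nbf_profile}.
#' @param assumptions an \code{nbf_assumptions}.
#' @return US$ (scalar), NA when required indicators are missing.
#' @export
child_mortality_loss <- function(deaths, profile, assumptions = nbf_assumptions()) {
  if (is.na(deaths)) return(NA_real_)
  if (is.na(profile$gni_per_capita) || is.na(profile$life_expectancy))
    return(NA_real_)
  end <- working_end_age(profile, assumptions)
  if (end <= assumptions$work_start_age) {
    warning(sprintf("%s: life expectancy below working age; loss 0",
                    profile$country_code))
    return(0)
  }
  pv <- present_value(earnings_stream(
    profile$gni_per_capita, assumptions$work_start_age, end,
    assumptions$gdp_growth, assumptions$discount_rate,
    stream_scale(profile, assumptions)))
  deaths * pv
}

#' Future earnings lost to attributable maternal mortality
#'
#' For each maternal pathway, deaths forfeit earnings over the foregone
#' productive years between the mean age of the pathway's mortality and the
#' earlier of retirement and life expectancy; a pathway whose mean age at
#' death is past that end point contributes nothing.
#'
#' @param burdens named list of \code{nbf_pathway_burden} for
#'   breast_cancer, ovarian_cancer, t2dm.
#' @param profile an \code{nbf_profile}.
#' @param assumptions an \code{nbf_assumptions}.
#' @return US$ (scalar); NA when no pathway could be computed (mean age at
#'   death or deaths missing for all of them).
#' @export
maternal_mortality_loss <- function(burdens, profile,
                                    assumptions = nbf_assumptions()) {
  if (is.na(profile$gni_per_capita) || is.na(profile$life_expectancy))
    return(NA_real_)
  end <- working_end_age(profile, assumptions)
  sc <- stream_scale(profile, assumptions, maternal = TRUE)
  total <- 0
  any_done <- FALSE
  for (b in burdens) {
    if (!b$computed || is.na(b$attributable_deaths)) next
    age <- profile$epidemiology[[b$pathway]]$mean_age_at_death
    if (is.na(age)) next
    any_done <- TRUE
    if (age >= end) next  # no productive years remain
    pv <- present_value(earnings_stream(
      profile$gni_per_capita, age, end,
      assumptions$gdp_growth, assumptions$discount_rate, sc))
    total <- total + b$attributable_deaths * pv
  }
  if (!any_done) return(NA_real_)
  total
}

#' Number of children in the cohort bearing the cognitive deficit
#'
#' Default exposure mode: children not exclusively breastfed below 6 months;
#' alternative: children not breastfed at 6 months. Both act on the one-year
#' birth cohort.
#'
#' @param profile an \code{nbf_profile}.
#' @param assumptions an \code{nbf_assumptions}.
#' @return count, NA when the needed prevalence is missing.
#' @export
cognitive_exposed <- function(profile, assumptions = nbf_assumptions()) {
  if (is.na(profile$births_annual)) return(NA_real_)
  share_bf <- switch(assumptions$cognitive_exposure_mode,
    exclusive_lt6m = profile$prevalence$band_0_5m[["exclusive"]],
    bf_at_6m = profile$prevalence$bf_at_6m)
  if (is.na(share_bf)) return(NA_real_)
  profile$births_annual * (1 - share_bf)
}

#' Future earnings lost to cognitive deficit
#'
#' Each exposed child loses iq_gain IQ points, each point costing
#' earnings_per_iq of the earnings stream over the productive years.
#'
#' @param n_exposed children bearing the deficit (see
#'   \code{\link{cognitive_exposed}}).
#' @param profile an \code{nbf_profile}.
#' @param assumptions an \code{nbf_assumptions}.
#' @return US$ (scalar), NA when required indicators are missing.
#' @export
cognitive_loss <- function(n_exposed, profile, assumptions = nbf_assumptions()) {
  if (is.na(n_exposed)) return(NA_real_)
  if (is.na(profile$gni_per_capita) || is.na(profile$life_expectancy))
    return(NA_real_)
  end <- working_end_age(profile, assumptions)
  if (end <= assumptions$work_start_age) return(0)
  pv <- present_value(earnings_stream(
    profile$gni_per_capita, assumptions$work_start_age, end,
    assumptions$gdp_growth, assumptions$discount_rate,
    stream_scale(profile, assumptions)))
  n_exposed * pv * assumptions$iq_gain * assumptions$earnings_per_iq
}
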