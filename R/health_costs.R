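# Health-system treatment costs and household formula affordability.

#' Inflate a unit cost by a cumulative CPI multiplier
#'
#' WHO-CHOICE-style unit costs are published for an earlier base year and are
#' brought to the analysis base year with a country-specific cumulative CPI
#' multiplier.
#'
#' @param cost US$ unit cost (scalar or vector).
#' @param cpi_multiplier cumulative inflation multiplier, > 0.
#' @return inflated cost(s).
#' @export
inflate_unit_cost <- function(cost, cpi_multiplier) {
  if (length(cpi_multiplier) != 1L || is.na(cpi_multiplier) ||
      cpi_multiplier <= 0)
    stop("cpi_multiplier must be a positive scalar")
  cost * cpi_multiplier
}

#' Treatment cost of an acute child pathway through the care-seeking cascade
#'
#' Attributable cases are taken through: share taken to a health facility,
#' split into outpatient vs inpatient care, distributed over facility levels,
#' and costed at the level-specific unit cost per outpatient visit or
#' inpatient bed day.
#'
#' @param burden an \code{nbf_pathway_burden} for diarrhoea or pneumonia.
#' @param cascade the pathway's care-seeking cascade (one element of an
#'   \code{nbf_cascade}).
#' @param costs an \code{nbf_unit_costs} whose facility-level unit costs are
#'   already in analysis-base-year dollars (see
#'   \code{\link{inflate_unit_cost}}).
#' @return object of class \code{nbf_treatment_cost} with outpatient and
#'   inpatient case counts and costs; \code{total_cost} is their sum.
#' @export
child_treatment_cost <- function(burden, cascade, costs) {
  nc <- function(reason) structure(
    list(pathway = burden$pathway, outpatient_cases = NA_real_,
         inpatient_cases = NA_real_, outpatient_cost = NA_real_,
         inpatient_cost = NA_real_, total_cost = NA_real_,
         computed = FALSE, reason = reason), class = "nbf_treatment_cost")
  if (!burden$computed) return(nc(paste("burden not computed:", burden$reason)))
  mix_out <- cascade$facility_mix_outpatient
  mix_in <- cascade$facility_mix_inpatient
  if (anyNA(cascade$pct_taken_to_facility) || anyNA(cascade$pct_inpatient_given_care) ||
      anyNA(mix_out) || anyNA(mix_in))
    return(nc("care-seeking cascade not available"))
  uc_out <- costs$outpatient_visit_cost
  uc_in <- costs$inpatient_day_cost
  # a missing unit cost only blocks the computation where the mix uses it
  if (anyNA(uc_out[mix_out > 0]) || anyNA(uc_in[mix_in > 0]))
    return(nc("unit cost missing at a facility level with nonzero mix"))
  cared <- burden$attributable_cases * cascade$pct_taken_to_facility
  inpat <- cared * cascade$pct_inpatient_given_care
  outpat <- cared - inpat
  out_cost <- outpat * cascade$visits_per_outpatient_case *
    sum(mix_out * uc_out, na.rm = TRUE)
  in_cost <- inpat * cascade$bed_days_per_inpatient_case *
    sum(mix_in * uc_in, na.rm = TRUE)
  structure(list(pathway = burden$pathway, outpatient_cases = outpat,
                 inpatient_cases = inpat, outpatient_cost = out_cost,
                 inpatient_cost = in_cost, total_cost = out_cost + in_cost,
                 computed = TRUE, reason = NULL),
            class = "nbf_treatment_cost")
}

#' @export
print.nbf_treatment_cost <- function(x, ...) {
  if (!x$computed) {
    cat(sprintf("<treatment cost> %s: not computed (%s)\n", x$pathway, x$reason))
  } else {
    cat(sprintf("<treatment cost> %s: US$%.0f (outpatient %.0f cases/US$%.0f, inpatient %.0f cases/US$%.0f)\n",
                x$pathway, x$total_cost, x$outpatient_cases, x$outpatient_cost,
                x$inpatient_cases, x$inpatient_cost))
  }
  invisible(x)
}

#' Treatment cost of attributable type II diabetes in women
#'
#' Attributable cases x share of cases diagnosed x annual health expenditure
#' per diagnosed case.
#'
#' @param burden an \code{nbf_pathway_burden} for the t2dm pathway.
#' @param costs an \code{nbf_unit_costs}.
#' @return US$ (scalar), or NA when inputs are unavailable.
#' @export
t2dm_treatment_cost <- function(burden, costs) {
  if (!burden$computed || is.na(burden$attributable_cases)) return(NA_real_)
  if (is.na(costs$pct_t2dm_diagnosed) || is.na(costs$t2dm_expenditure_per_case))
    return(NA_real_)
  burden$attributable_cases * costs$pct_t2dm_diagnosed *
    costs$t2dm_expenditure_per_case
}

#' Formula cost as a share of household earnings
#'
#' Cost of feeding a child formula from birth to age two (containers x unit
#' price of a 900-g container) divided by 24 months of mean earnings.
#'
#' @param costs an \code{nbf_unit_costs}; a country without its own formula
#'   price should carry the global mean price as proxy (the generator and
#'   reader do this).
#' @param profile an \code{nbf_profile} with \code{mean_monthly_wage}.
#' @return fraction of two years' earnings, or NA when the wage is missing or
#'   zero (never infinity).
#' @export
formula_cost_share <- function(costs, profile) {
  w <- profile$mean_monthly_wage
  if (is.na(w) || w <= 0) return(NA_real_)
  if (is.na(costs$formula_price_per_900g) ||
      is.na(costs$formula_containers_birth_to_24m)) return(NA_real_)
  (costs$formula_containers_birth_to_24m * costs$formula_price_per_900g) /
    (w * 24)
}
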