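# Attributable burden: Levin population attributable fractions against a
# universal-breastfeeding counterfactual.

#' Population attributable fraction (multi-category Levin formula)
#'
#' PAF = (sum_c p_c RR_c - 1) / (sum_c p_c RR_c), the share of burden removed
#' if all exposure mass moved to the reference (recommended-practice,
#' lowest-risk) category. With all RR >= 1 the value lies in [0, 1).
#'
#' @param prevalence named fractions over exposure categories, summing to 1.
#' @param rr named relative risks over the same categories; exactly one
#'   reference category must have RR = 1.
#' @return the attributable fraction (scalar).
#' @export
paf <- function(prevalence, rr) {
  if (is.null(names(prevalence)) || is.null(names(rr)) ||
      !setequal(names(prevalence), names(rr)))
    stop("prevalence and rr must be named over the same exposure categories")
  rr <- rr[names(prevalence)]
  if (anyNA(prevalence) || anyNA(rr))
    stop("prevalence and rr must be complete (no NA)")
  if (abs(sum(prevalence) - 1) > 1e-6)
    stop(sprintf("prevalence must sum to 1 (got %.8f)", sum(prevalence)))
  if (any(rr <= 0)) stop("all relative risks must be > 0")
  if (!any(abs(rr - 1) < 1e-12)) stop("no reference category with RR = 1")
  s <- sum(prevalence * rr)
  (s - 1) / s
}

new_pathway_burden <- function(pathway, cases, deaths, paf_cases, paf_deaths,
                               computed = TRUE, reason = NULL) {
  structure(list(pathway = pathway,
                 attributable_cases = cases, attributable_deaths = deaths,
                 paf_used = c(cases = paf_cases, deaths = paf_deaths),
                 computed = computed, reason = reason),
            class = "nbf_pathway_burden")
}

not_computed <- function(pathway, reason) {
  new_pathway_burden(pathway, NA_real_, NA_real_, NA_real_, NA_real_,
                     computed = FALSE, reason = reason)
}

#' @export
print.nbf_pathway_burden <- function(x, ...) {
  if (!x$computed) {
    cat(sprintf("<pathway burden> %s: not computed (%s)\n", x$pathway, x$reason))
  } else {
    cat(sprintf("<pathway burden> %s: %.0f attributable cases, %s deaths (PAF %.3f/%.3f)\n",
                x$pathway, x$attributable_cases,
                if (is.na(x$attributable_deaths)) "-" else
                  sprintf("%.0f", x$attributable_deaths),
                x$paf_used[["cases"]], x$paf_used[["deaths"]]))
  }
  invisible(x)
}

#' Attributable burden for an acute child pathway
#'
#' Diarrhoea and pneumonia in children 0--23 months. A Levin PAF is computed
#' per exposure age band (0--5 months over exclusive/predominant/partial/none;
#' 6--23 months over any/none) and the two band PAFs are pooled weighted by
#' each band's share of cases (for cases) and of deaths (for deaths); the
#' pooled fraction is applied to observed incidence and deaths.
#'
#' @param profile an \code{nbf_profile}.
#' @param pathway \code{"diarrhoea"} or \code{"pneumonia"}.
#' @param weights optional length-2 overrides for the 0--5 month band weight,
#'   named \code{c(cases=, deaths=)}; defaults to the profile's burden shares.
#' @return an \code{nbf_pathway_burden}.
#' @export
child_pathway_burden <- function(profile, pathway = c("diarrhoea", "pneumonia"),
                                 weights = NULL) {
  pathway <- match.arg(pathway)
  epi <- profile$epidemiology[[pathway]]
  pv <- profile$prevalence
  if (is.na(epi$incidence) || is.na(epi$deaths))
    return(not_computed(pathway, "incidence/deaths not available"))
  if (anyNA(pv$band_0_5m) || anyNA(pv$band_6_23m))
    return(not_computed(pathway, "breastfeeding prevalence not available"))
  paf05 <- paf(pv$band_0_5m, profile$rr[[pathway]]$band_0_5m)
  paf623 <- paf(pv$band_6_23m, profile$rr[[pathway]]$band_6_23m)
  w_cases <- if (!is.null(weights)) weights[["cases"]] else epi$share_cases_0_5m
  w_deaths <- if (!is.null(weights)) weights[["deaths"]] else epi$share_deaths_0_5m
  paf_cases <- w_cases * paf05 + (1 - w_cases) * paf623
  paf_deaths <- w_deaths * paf05 + (1 - w_deaths) * paf623
  new_pathway_burden(pathway, epi$incidence * paf_cases,
                     epi$deaths * paf_deaths, paf_cases, paf_deaths)
}

#' Attributable childhood obesity cases
#'
#' Two-category Levin PAF with never-breastfed children as the exposed group
#' and ever-breastfed as reference, applied to annual incident childhood
#' obesity cases. Deaths are not computed for this pathway.
#'
#' @param profile an \code{nbf_profile}.
#' @return an \code{nbf_pathway_burden}.
#' @export
obesity_burden <- function(profile) {
  epi <- profile$epidemiology$obesity
  eb <- profile$prevalence$ever_breastfed
  if (is.na(epi$incidence))
    return(not_computed("obesity", "obesity incidence not available"))
  if (is.na(eb))
    return(not_computed("obesity", "ever-breastfed prevalence not available"))
  p <- c(ever = eb, never = 1 - eb)
  f <- paf(p, profile$rr$obesity[names(p)])
  new_pathway_burden("obesity", epi$incidence * f, NA_real_, f, NA_real_)
}

#' Attributable burden for a maternal pathway
#'
#' Breast cancer, ovarian cancer and type II diabetes in women, driven by the
#' population's attainment of recommended lifetime breastfeeding. The default
#' mode computes a two-category Levin PAF with exposed share
#' \code{1 - lifetime_duration_level} and applies the same fraction to
#' incidence (cases) and deaths (the mortality effect is assumed equal in
#' magnitude to the morbidity effect). The \code{"literal"} mode instead
#' evaluates the plain product incidence x (RR - 1) x shortfall, kept for
#' audit comparisons; it is unbounded and not used by the estimator.
#'
#' @param profile an \code{nbf_profile}.
#' @param pathway \code{"breast_cancer"}, \code{"ovarian_cancer"} or
#'   \code{"t2dm"}.
#' @param mode \code{"paf"} (default) or \code{"literal"}.
#' @return an \code{nbf_pathway_burden}.
#' @export
maternal_pathway_burden <- function(profile,
                                    pathway = c("breast_cancer", "ovarian_cancer", "t2dm"),
                                    mode = c("paf", "literal")) {
  pathway <- match.arg(pathway)
  mode <- match.arg(mode)
  epi <- profile$epidemiology[[pathway]]
  level <- profile$prevalence$lifetime_duration_level
  if (is.na(level))
    return(not_computed(pathway, "lifetime breastfeeding level not available"))
  if (is.na(epi$incidence) && is.na(epi$deaths))
    return(not_computed(pathway, "incidence/deaths not available"))
  rrv <- profile$rr[[pathway]]
  if (mode == "literal") {
    shortfall <- 1 - level
    rr_exposed <- rrv[["below"]]
    cases <- if (is.na(epi$incidence)) NA_real_ else
      epi$incidence * (rr_exposed - 1) * shortfall
    deaths <- if (is.na(epi$deaths)) NA_real_ else
      epi$deaths * (rr_exposed - 1) * shortfall
    return(new_pathway_burden(pathway, cases, deaths, NA_real_, NA_real_))
  }
  p <- c(recommended = level, below = 1 - level)
  f <- paf(p, rrv[names(p)])
  cases <- if (is.na(epi$incidence)) NA_real_ else epi$incidence * f
  deaths <- if (is.na(epi$deaths)) NA_real_ else epi$deaths * f
  new_pathway_burden(pathway, cases, deaths, f, f)
}
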