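# The estimator: per-country results and the nbf_estimate fitting surface.

#' Estimate the full cost of not breastfeeding for one country
#'
#' Runs the whole cascade for a single country: attributable burden per
#' pathway, health-system treatment costs (with CPI-adjusted unit costs),
#' household formula affordability, and discounted future economic losses
#' from child mortality, maternal mortality and cognitive deficit. Components
#' whose inputs are missing are reported as not computed (NA) and listed in
#' \code{missing}; they are never silently zero. The total loss is the sum of
#' the available components.
#'
#' @param profile an \code{nbf_profile}.
#' @param assumptions an \code{nbf_assumptions}.
#' @return object of class \code{nbf_country_result}.
#' @export
estimate_country <- function(profile, assumptions = nbf_assumptions()) {
  burdens <- list(
    diarrhoea = child_pathway_burden(profile, "diarrhoea"),
    pneumonia = child_pathway_burden(profile, "pneumonia"),
    obesity = obesity_burden(profile),
    breast_cancer = maternal_pathway_burden(profile, "breast_cancer"),
    ovarian_cancer = maternal_pathway_burden(profile, "ovarian_cancer"),
    t2dm = maternal_pathway_burden(profile, "t2dm"))

  # CPI adjustment applies to the WHO-CHOICE-style facility unit costs only
  uc <- profile$unit_costs
  cpi <- profile$cpi_cumulative_2008_2017
  if (!is.na(cpi) && cpi > 0) {
    uc$outpatient_visit_cost <- inflate_unit_cost(uc$outpatient_visit_cost, cpi)
    uc$inpatient_day_cost <- inflate_unit_cost(uc$inpatient_day_cost, cpi)
  }
  treat <- list(
    diarrhoea = child_treatment_cost(burdens$diarrhoea,
                                     profile$cascade$diarrhoea, uc),
    pneumonia = child_treatment_cost(burdens$pneumonia,
                                     profile$cascade$pneumonia, uc))
  cost_t2dm <- t2dm_treatment_cost(burdens$t2dm, uc)
  health <- c(diarrhoea = treat$diarrhoea$total_cost,
              pneumonia = treat$pneumonia$total_cost,
              t2dm = cost_t2dm)
  health_total <- if (all(is.na(health))) NA_real_ else sum(health, na.rm = TRUE)

  loss_child <- child_mortality_loss(
    sum_or_na(burdens$diarrhoea$attributable_deaths,
              burdens$pneumonia$attributable_deaths),
    profile, assumptions)
  loss_maternal <- maternal_mortality_loss(
    burdens[c("breast_cancer", "ovarian_cancer", "t2dm")], profile, assumptions)
  loss_cog <- cognitive_loss(cognitive_exposed(profile, assumptions),
                             profile, assumptions)

  components <- c(health_system = health_total,
                  child_mortality = loss_child,
                  maternal_mortality = loss_maternal,
                  cognitive = loss_cog)
  missing <- names(components)[is.na(components)]
  loss_total <- if (all(is.na(components))) NA_real_ else
    sum(components, na.rm = TRUE)
  pct_gni <- if (is.na(loss_total) || is.na(profile$gni_total) ||
                 profile$gni_total <= 0) NA_real_ else
    loss_total / profile$gni_total

  structure(list(
    country_code = profile$country_code, region = profile$region,
    income_group = profile$income_group, gni_total = profile$gni_total,
    burdens = burdens, treatment = treat,
    health_cost = health, health_cost_total = health_total,
    formula_cost_share = formula_cost_share(uc, profile),
    loss_child_mortality = loss_child,
    loss_maternal_mortality = loss_maternal,
    loss_cognitive = loss_cog, loss_total = loss_total,
    loss_total_pct_gni = pct_gni, missing = missing),
    class = "nbf_country_result")
}

sum_or_na <- function(...) {
  x <- c(...)
  if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
}

#' @export
print.nbf_country_result <- function(x, ...) {
  cat(sprintf("<nbf_country_result> %s\n", x$country_code))
  cat(sprintf("  health-system cost US$%s; losses: child mortality US$%s, maternal US$%s, cognitive US$%s\n",
              fmt_usd(x$health_cost_total), fmt_usd(x$loss_child_mortality),
              fmt_usd(x$loss_maternal_mortality), fmt_usd(x$loss_cognitive)))
  cat(sprintf("  total US$%s (%s%% of GNI)%s\n", fmt_usd(x$loss_total),
              if (is.na(x$loss_total_pct_gni)) "-" else
                sprintf("%.2f", 100 * x$loss_total_pct_gni),
              if (length(x$missing)) paste0("; not computed: ",
                                            paste(x$missing, collapse = ", "))
              else ""))
  invisible(x)
}

fmt_usd <- function(x) {
  if (is.na(x)) return("-")
  if (x >= 1e9) sprintf("%.2fb", x / 1e9)
  else if (x >= 1e6) sprintf("%.1fm", x / 1e6)
  else format(round(x), big.mark = ",")
}

#' Flatten country results into a data frame
#'
#' @param x an \code{nbf_country_result} or a list of them.
#' @param ... unused.
#' @return one row per country with burden, cost and loss columns; NA marks a
#'   component that was not computed.
#' @export
as.data.frame.nbf_country_result <- function(x, ...) {
  b <- x$burdens
  data.frame(
    country_code = x$country_code, region = x$region,
    income_group = x$income_group, gni_total = x$gni_total,
    cases_diarrhoea = b$diarrhoea$attributable_cases,
    cases_pneumonia = b$pneumonia$attributable_cases,
    cases_obesity = b$obesity$attributable_cases,
    cases_breast_cancer = b$breast_cancer$attributable_cases,
    cases_ovarian_cancer = b$ovarian_cancer$attributable_cases,
    cases_t2dm = b$t2dm$attributable_cases,
    deaths_diarrhoea = b$diarrhoea$attributable_deaths,
    deaths_pneumonia = b$pneumonia$attributable_deaths,
    deaths_child = sum_or_na(b$diarrhoea$attributable_deaths,
                             b$pneumonia$attributable_deaths),
    deaths_breast_cancer = b$breast_cancer$attributable_deaths,
    deaths_ovarian_cancer = b$ovarian_cancer$attributable_deaths,
    deaths_t2dm = b$t2dm$attributable_deaths,
    deaths_maternal = sum_or_na(b$breast_cancer$attributable_deaths,
                                b$ovarian_cancer$attributable_deaths,
                                b$t2dm$attributable_deaths),
    cost_diarrhoea = unname(x$health_cost[["diarrhoea"]]),
    cost_pneumonia = unname(x$health_cost[["pneumonia"]]),
    cost_t2dm = unname(x$health_cost[["t2dm"]]),
    cost_health_total = x$health_cost_total,
    formula_cost_share = x$formula_cost_share,
    loss_child_mortality = x$loss_child_mortality,
    loss_maternal_mortality = x$loss_maternal_mortality,
    loss_cognitive = x$loss_cognitive,
    loss_total = x$loss_total,
    loss_total_pct_gni = x$loss_total_pct_gni,
    stringsAsFactors = FALSE)
}

results_frame <- function(results) {
  do.call(rbind, lapply(results, as.data.frame))
}

#' Estimate the cost of not breastfeeding over a set of countries
#'
#' The main fitting function. Takes country profiles (a list, or a directory
#' of long-format indicator CSVs), runs the per-country estimator under the
#' given assumptions, aggregates by region, income group and globally with
#' strict no-extrapolation sums, and optionally evaluates sensitivity
#' scenarios.
#'
#' @param countries list of \code{nbf_profile} objects, or a directory path
#'   readable by \code{\link{read_country_tables}}.
#' @param assumptions an \code{nbf_assumptions}.
#' @param scenarios optional list of \code{nbf_scenario} for sensitivity
#'   analysis (see \code{\link{run_sensitivity}}).
#' @return object of class \code{nbf_estimate} with elements
#'   \code{results} (per-country \code{nbf_country_result}s), \code{table}
#'   (per-country data frame), \code{by_region}, \code{by_income},
#'   \code{global} (aggregates), \code{sensitivity} (scenario grid or NULL),
#'   \code{assumptions}, and \code{call}.
#' @examples
#' fit <- nbf_estimate(simulate_countries(10, seed = 1))
#' summary(fit)
#' @export
nbf_estimate <- function(countries, assumptions = nbf_assumptions(),
                         scenarios = NULL) {
  if (is.character(countries) && length(countries) == 1L)
    countries <- read_country_tables(countries)
  stopifnot(length(countries) >= 1L,
            all(vapply(countries, inherits, logical(1), "nbf_profile")))
  results <- lapply(countries, estimate_country, assumptions = assumptions)
  names(results) <- vapply(results, `[[`, character(1), "country_code")
  tab <- results_frame(results)
  sens <- if (!is.null(scenarios))
    run_sensitivity(countries, scenarios, assumptions) else NULL
  structure(list(results = results, table = tab,
                 by_region = aggregate_results(results, by = "region"),
                 by_income = aggregate_results(results, by = "income"),
                 global = aggregate_results(results, by = "global"),
                 sensitivity = sens, assumptions = assumptions,
                 n_countries = length(results), call = match.call()),
            class = "nbf_estimate")
}

#' @export
print.nbf_estimate <- function(x, ...) {
  g <- x$global
  cat(sprintf("<nbf_estimate> %d countries\n", x$n_countries))
  cat(sprintf("  attributable child deaths: %s; maternal deaths: %s\n",
              format(round(g$deaths_child), big.mark = ","),
              format(round(g$deaths_maternal), big.mark = ",")))
  cat(sprintf("  health-system cost US$%s; total economic loss US$%s (%.2f%% of GNI)\n",
              fmt_usd(g$cost_health_total), fmt_usd(g$loss_total),
              100 * g$pct_gni))
  invisible(x)
}

#' @export
summary.nbf_estimate <- function(object, ...) {
  structure(list(global = object$global, by_region = object$by_region,
                 by_income = object$by_income,
                 sensitivity = object$sensitivity,
                 assumptions = object$assumptions,
                 n_countries = object$n_countries),
            class = "summary.nbf_estimate")
}

#' @export
print.summary.nbf_estimate <- function(x, ...) {
  cat(sprintf("Cost of not breastfeeding -- %d countries\n\n", x$n_countries))
  show <- c("group", "n_countries", "deaths_child", "deaths_maternal",
            "cost_health_total", "loss_child_mortality",
            "loss_maternal_mortality", "loss_cognitive", "loss_total",
            "pct_gni")
  cat("By region:\n")
  print(round_agg(x$by_region[, show]))
  cat("\nBy income group:\n")
  print(round_agg(x$by_income[, show]))
  cat("\nGlobal:\n")
  print(round_agg(x$global[, show]))
  if (!is.null(x$sensitivity)) {
    cat("\nSensitivity scenarios (global):\n")
    print(x$sensitivity[x$sensitivity$group == "global",
                        c("scenario", "discount_rate", "gdp_growth",
                          "loss_total")])
  }
  invisible(x)
}

# display rounding: counts to integers, US$ to millions 2dp, %GNI to 2dp
round_agg <- function(df) {
  for (cn in names(df)) {
    if (startsWith(cn, "deaths_") || startsWith(cn, "cases_"))
      df[[cn]] <- round(df[[cn]])
    if (startsWith(cn, "cost_") || startsWith(cn, "loss_"))
      df[[cn]] <- round(df[[cn]] / 1e6, 2)
    if (cn == "pct_gni") df[[cn]] <- round(100 * df[[cn]], 2)
  }
  names(df) <- sub("^(cost|loss)_(.*)$", "\\1_\\2_usd_m", names(df))
  df
}

#' Plot loss components by region
#'
#' Stacked bars of health-system cost and mortality/cognitive losses per
#' region, in US$ billions.
#'
#' @param x an \code{nbf_estimate}.
#' @param ... passed to \code{barplot}.
#' @export
plot.nbf_estimate <- function(x, ...) {
  r <- x$by_region
  m <- t(as.matrix(r[, c("cost_health_total", "loss_child_mortality",
                         "loss_maternal_mortality", "loss_cognitive")])) / 1e9
  m[is.na(m)] <- 0
  colnames(m) <- abbreviate(r$group, 12)
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(m, las = 2, ylab = "US$ billion / year",
                    col = grDevices::hcl.colors(4, "viridis"),
                    legend.text = c("health system", "child mortality",
                                    "maternal mortality", "cognitive"),
                    args.legend = list(x = "topleft", bty = "n", cex = 0.8),
                    ...)
  invisible(x)
}
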