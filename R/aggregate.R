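# No-extrapolation aggregation and the sensitivity scenario grid.

agg_fields <- c("cases_diarrhoea", "cases_pneumonia", "cases_obesity",
                "cases_breast_cancer", "cases_ovarian_cancer", "cases_t2dm",
                "deaths_diarrhoea", "deaths_pneumonia", "deaths_child",
                "deaths_breast_cancer", "deaths_ovarian_cancer", "deaths_t2dm",
                "deaths_maternal", "cost_diarrhoea", "cost_pneumonia",
                "cost_t2dm", "cost_health_total", "loss_child_mortality",
                "loss_maternal_mortality", "loss_cognitive", "loss_total")

#' Aggregate country results into group totals
#'
#' Cumulative sums over the countries with available data, never extrapolated
#' to the group's full population: each field is summed over the countries
#' where it was computed, a country with a missing component contributes
#' nothing (not zero) to that component, and the per-field inclusion counts
#' are part of the result. The \%-of-GNI figure divides each group's summed
#' total loss by the summed GNI of the same included country set.
#'
#' @param results list of \code{nbf_country_result} (or the data frame from
#'   \code{as.data.frame}).
#' @param by \code{"region"}, \code{"income"} or \code{"global"}.
#' @return data frame of class \code{nbf_aggregate}, one row per group, with
#'   summed fields, \code{n_countries} (countries in the group) and an
#'   \code{n_<field>} inclusion count per summed field.
#' @export
aggregate_results <- function(results, by = c("region", "income", "global")) {
  by <- match.arg(by)
  df <- if (is.data.frame(results)) results else results_frame(results)
  key <- switch(by, region = df$region, income = df$income_group,
                global = rep("global", nrow(df)))
  groups <- switch(by,
    region = intersect(nbf_regions, unique(key)),
    income = intersect(nbf_income_groups, unique(key)),
    global = "global")
  rows <- lapply(groups, function(g) {
    sub <- df[key == g, , drop = FALSE]
    sums <- vapply(agg_fields, function(f) {
      x <- sub[[f]]
      if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
    }, numeric(1))
    ns <- vapply(agg_fields, function(f) sum(!is.na(sub[[f]])), numeric(1))
    inc <- !is.na(sub$loss_total) & !is.na(sub$gni_total)
    gni <- sum(sub$gni_total[inc])
    pct <- if (gni > 0) sum(sub$loss_total[inc]) / gni else NA_real_
    cbind(data.frame(group = g, n_countries = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sums)),
          data.frame(gni_total = gni, pct_gni = pct),
          stats::setNames(as.data.frame(as.list(ns)), paste0("n_", agg_fields)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nbf_aggregate", "data.frame")
  out
}

#' Sum printed table rows for one grouping
#'
#' Reproduces a published table's "Total" row from its printed group rows:
#' sums every numeric column over the rows of the requested grouping. Used to
#' verify the aggregation against the shipped table fixtures.
#'
#' @param table a data frame with a \code{grouping} column (\code{"region"} /
#'   \code{"income"}) and numeric value columns.
#' @param grouping which rows to sum.
#' @return named numeric vector of column sums.
#' @export
aggregate_printed_rows <- function(table, grouping = c("region", "income")) {
  grouping <- match.arg(grouping)
  sub <- table[table$grouping == grouping, , drop = FALSE]
  num <- vapply(sub, is.numeric, logical(1))
  colSums(sub[, num, drop = FALSE])
}

#' Run the sensitivity scenario grid
#'
#' Re-computes every discount/growth-dependent component under each scenario.
#' Attributable burden and health-system costs do not depend on the rates and
#' are identical across scenarios; only the future-loss components (and hence
#' totals and \%GNI) move.
#'
#' @param countries list of \code{nbf_profile}.
#' @param scenarios list of \code{nbf_scenario}; defaults to the default /
#'   conservative / optimistic triple.
#' @param assumptions base \code{nbf_assumptions} whose rates each scenario
#'   overrides.
#' @param by grouping passed to \code{\link{aggregate_results}}; the global
#'   row is always included.
#' @return data frame with one row per scenario x group carrying the summed
#'   loss components, total and \%GNI.
#' @export
run_sensitivity <- function(countries,
                            scenarios = lapply(c("default", "conservative",
                                                 "optimistic"), nbf_scenario),
                            assumptions = nbf_assumptions(),
                            by = "region") {
  stopifnot(length(scenarios) >= 1L)
  rows <- lapply(scenarios, function(sc) {
    a <- with_scenario(assumptions, sc)
    res <- lapply(countries, estimate_country, assumptions = a)
    agg <- rbind(aggregate_results(res, by = by),
                 aggregate_results(res, by = "global"))
    keep <- c("group", "n_countries", "cost_health_total",
              "loss_child_mortality", "loss_maternal_mortality",
              "loss_cognitive", "loss_total", "pct_gni")
    cbind(data.frame(scenario = sc$label, discount_rate = sc$discount_rate,
                     gdp_growth = sc$gdp_growth, stringsAsFactors = FALSE),
          as.data.frame(agg)[, keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
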