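# Long-format CSV ingestion/serialisation and the end-to-end pipeline.
#
# Dialect: UTF-8, comma separated, "." decimal, no thousands separators in
# files (space-grouped numbers as printed in publications are stripped by the
# loader). Every file holds columns country_code, indicator, stratum, value,
# year, source.

csv_files <- c("demography.csv", "economy.csv", "breastfeeding.csv",
               "epidemiology.csv", "relative_risks.csv", "care_seeking.csv",
               "unit_costs.csv")

fmt_val <- function(x) {
  if (is.character(x)) x else sprintf("%.17g", x)
}

long_rows <- function(code, indicator, stratum, value) {
  keep <- !vapply(value, function(v) is.na(v) || (is.character(v) && v == ""),
                  logical(1))
  if (!any(keep)) return(NULL)
  data.frame(country_code = code, indicator = indicator[keep],
             stratum = stratum[keep],
             value = vapply(value[keep], fmt_val, character(1)),
             year = "", source = "synthetic", stringsAsFactors = FALSE)
}

flatten_profile <- function(p) {
  rows <- list()
  add <- function(file, indicator, stratum, value)
    rows[[length(rows) + 1L]] <<- cbind(
      file = file, long_rows(p$country_code, indicator, stratum, value))

  add("demography.csv",
      c("region", "income_group", "births_annual", "children_0_23m",
        "population", "life_expectancy", "retirement_age"),
      rep("", 7),
      list(p$region, p$income_group, p$births_annual, p$children_0_23m,
           p$population, p$life_expectancy, p$retirement_age))
  add("economy.csv",
      c("gni_total", "gni_per_capita", "wage_share", "lfpr_female",
        "mean_monthly_wage", "cpi_cumulative_2008_2017"), rep("", 6),
      list(p$gni_total, p$gni_per_capita, p$wage_share, p$lfpr_female,
           p$mean_monthly_wage, p$cpi_cumulative_2008_2017))
  pv <- p$prevalence
  add("breastfeeding.csv",
      c(rep("bf_prevalence_0_5m", 4), rep("bf_prevalence_6_23m", 2),
        "ever_breastfed", "bf_at_6m", "lifetime_duration_level"),
      c(names(pv$band_0_5m), names(pv$band_6_23m), "", "", ""),
      as.list(c(pv$band_0_5m, pv$band_6_23m, pv$ever_breastfed, pv$bf_at_6m,
                pv$lifetime_duration_level)))
  for (pw in nbf_pathways) {
    e <- p$epidemiology[[pw]]
    add("epidemiology.csv", rep(pw, length(e)), names(e), e)
    rr <- p$rr[[pw]]
    if (is.list(rr)) {
      add("relative_risks.csv", rep(pw, length(unlist(rr))),
          c(paste0("band_0_5m:", names(rr$band_0_5m)),
            paste0("band_6_23m:", names(rr$band_6_23m))),
          as.list(unlist(rr, use.names = FALSE)))
    } else {
      add("relative_risks.csv", rep(pw, length(rr)), names(rr), as.list(rr))
    }
  }
  for (pw in c("diarrhoea", "pneumonia")) {
    cs <- p$cascade[[pw]]
    add("care_seeking.csv", rep(pw, 12),
        c("pct_taken_to_facility", "pct_inpatient_given_care",
          "visits_per_outpatient_case", "bed_days_per_inpatient_case",
          paste0("mix_outpatient:", nbf_facility_levels),
          paste0("mix_inpatient:", nbf_facility_levels)),
        as.list(c(cs$pct_taken_to_facility, cs$pct_inpatient_given_care,
                  cs$visits_per_outpatient_case, cs$bed_days_per_inpatient_case,
                  cs$facility_mix_outpatient, cs$facility_mix_inpatient)))
  }
  uc <- p$unit_costs
  add("unit_costs.csv",
      c(rep("outpatient_visit_cost", 4), rep("inpatient_day_cost", 4),
        "t2dm_expenditure_per_case", "pct_t2dm_diagnosed",
        "formula_price_per_900g", "formula_containers_birth_to_24m"),
      c(nbf_facility_levels, nbf_facility_levels, "", "", "", ""),
      as.list(c(uc$outpatient_visit_cost, uc$inpatient_day_cost,
                uc$t2dm_expenditure_per_case, uc$pct_t2dm_diagnosed,
                uc$formula_price_per_900g, uc$formula_containers_birth_to_24m)))
  do.call(rbind, rows)
}

#' Write country profiles as long-format indicator CSVs
#'
#' Serialises profiles into the seven indicator files (demography, economy,
#' breastfeeding, epidemiology, relative_risks, care_seeking, unit_costs),
#' each with columns \code{country_code, indicator, stratum, value, year,
#' source}. Missing (NA) indicators are omitted rather than written, so a
#' round trip preserves availability flags.
#'
#' @param profiles list of \code{nbf_profile}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_country_tables <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all <- do.call(rbind, lapply(profiles, flatten_profile))
  paths <- character(0)
  for (f in csv_files) {
    sub <- all[all$file == f, setdiff(names(all), "file"), drop = FALSE]
    path <- file.path(dir, f)
    utils::write.csv(sub, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  invisible(paths)
}

read_long_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("country_code", "indicator", "stratum", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required columns (%s)", basename(path),
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df$line <- seq_len(nrow(df)) + 1L                  # 1 = header line
  df
}

lv <- function(df, code, indicator, stratum = "") {
  hit <- df$country_code == code & df$indicator == indicator &
    df$stratum == stratum
  if (!any(hit)) return(NA_real_)
  row <- df[which(hit)[1L], ]
  # printed tables group digits with spaces; the loader strips them
  x <- suppressWarnings(as.numeric(gsub(" ", "", row$value, fixed = TRUE)))
  if (is.na(x) && nzchar(row$value))
    stop(sprintf("%s line %d: non-numeric value '%s' for indicator %s",
                 attr(df, "file"), row$line, row$value, indicator))
  x
}

lv_chr <- function(df, code, indicator) {
  hit <- df$country_code == code & df$indicator == indicator
  if (!any(hit)) return("")
  df$value[which(hit)[1L]]
}

lv_named <- function(df, code, indicator, strata, prefix = "") {
  stats::setNames(vapply(strata, function(s)
    lv(df, code, indicator, paste0(prefix, s)), numeric(1)), strata)
}

#' Read country profiles from long-format indicator CSVs
#'
#' Inverse of \code{\link{write_country_tables}}. All seven indicator files
#' must be present; a country may appear in only some of them, in which case
#' its profile is built with the absent indicators set NA and flagged.
#' Non-numeric value cells raise an error naming the file and line.
#'
#' @param dir directory containing the indicator CSVs.
#' @return list of \code{nbf_profile}, one per country code seen anywhere.
#' @export
read_country_tables <- function(dir) {
  paths <- file.path(dir, csv_files)
  absent <- !file.exists(paths)
  if (any(absent))
    stop("missing mandatory input file(s): ",
         paste(csv_files[absent], collapse = ", "))
  tabs <- lapply(paths, read_long_csv)
  names(tabs) <- csv_files
  for (f in csv_files) attr(tabs[[f]], "file") <- f

  codes <- sort(unique(unlist(lapply(tabs, `[[`, "country_code"))))
  bands05 <- c("exclusive", "predominant", "partial", "none")
  profiles <- lapply(codes, function(code) {
    dem <- tabs$demography.csv; eco <- tabs$economy.csv
    bf <- tabs$breastfeeding.csv; ep <- tabs$epidemiology.csv
    rr <- tabs$relative_risks.csv; cs <- tabs$care_seeking.csv
    uc <- tabs$unit_costs.csv

    acute_epi <- function(pw) list(
      incidence = lv(ep, code, pw, "incidence"),
      deaths = lv(ep, code, pw, "deaths"),
      share_cases_0_5m = lv(ep, code, pw, "share_cases_0_5m"),
      share_deaths_0_5m = lv(ep, code, pw, "share_deaths_0_5m"))
    mat_epi <- function(pw) list(
      incidence = lv(ep, code, pw, "incidence"),
      deaths = lv(ep, code, pw, "deaths"),
      mean_age_at_death = lv(ep, code, pw, "mean_age_at_death"))
    acute_rr <- function(pw) list(
      band_0_5m = lv_named(rr, code, pw, bands05, "band_0_5m:"),
      band_6_23m = lv_named(rr, code, pw, c("any", "none"), "band_6_23m:"))
    casc <- function(pw) list(
      pct_taken_to_facility = lv(cs, code, pw, "pct_taken_to_facility"),
      pct_inpatient_given_care = lv(cs, code, pw, "pct_inpatient_given_care"),
      visits_per_outpatient_case = lv(cs, code, pw, "visits_per_outpatient_case"),
      bed_days_per_inpatient_case = lv(cs, code, pw, "bed_days_per_inpatient_case"),
      facility_mix_outpatient = lv_named(cs, code, pw, nbf_facility_levels,
                                         "mix_outpatient:"),
      facility_mix_inpatient = lv_named(cs, code, pw, nbf_facility_levels,
                                        "mix_inpatient:"))

    nbf_profile(
      country_code = code,
      region = lv_chr(dem, code, "region"),
      income_group = lv_chr(dem, code, "income_group"),
      births_annual = lv(dem, code, "births_annual"),
      children_0_23m = lv(dem, code, "children_0_23m"),
      population = lv(dem, code, "population"),
      life_expectancy = lv(dem, code, "life_expectancy"),
      retirement_age = {
        x <- lv(dem, code, "retirement_age"); if (is.na(x)) 65 else x
      },
      gni_total = lv(eco, code, "gni_total"),
      gni_per_capita = lv(eco, code, "gni_per_capita"),
      wage_share = lv(eco, code, "wage_share"),
      lfpr_female = lv(eco, code, "lfpr_female"),
      mean_monthly_wage = lv(eco, code, "mean_monthly_wage"),
      cpi_cumulative_2008_2017 = {
        x <- lv(eco, code, "cpi_cumulative_2008_2017")
        if (is.na(x)) 1 else x
      },
      prevalence = nbf_prevalence(
        band_0_5m = lv_named(bf, code, "bf_prevalence_0_5m", bands05),
        band_6_23m = lv_named(bf, code, "bf_prevalence_6_23m", c("any", "none")),
        ever_breastfed = lv(bf, code, "ever_breastfed"),
        bf_at_6m = lv(bf, code, "bf_at_6m"),
        lifetime_duration_level = lv(bf, code, "lifetime_duration_level")),
      epidemiology = nbf_epidemiology(
        diarrhoea = acute_epi("diarrhoea"), pneumonia = acute_epi("pneumonia"),
        obesity = list(incidence = lv(ep, code, "obesity", "incidence")),
        breast_cancer = mat_epi("breast_cancer"),
        ovarian_cancer = mat_epi("ovarian_cancer"), t2dm = mat_epi("t2dm")),
      rr = nbf_rr_table(
        diarrhoea = acute_rr("diarrhoea"), pneumonia = acute_rr("pneumonia"),
        obesity = lv_named(rr, code, "obesity", c("ever", "never")),
        breast_cancer = lv_named(rr, code, "breast_cancer",
                                 c("recommended", "below")),
        ovarian_cancer = lv_named(rr, code, "ovarian_cancer",
                                  c("recommended", "below")),
        t2dm = lv_named(rr, code, "t2dm", c("recommended", "below"))),
      cascade = nbf_cascade(diarrhoea = casc("diarrhoea"),
                            pneumonia = casc("pneumonia")),
      unit_costs = nbf_unit_costs(
        outpatient_visit_cost = lv_named(uc, code, "outpatient_visit_cost",
                                         nbf_facility_levels),
        inpatient_day_cost = lv_named(uc, code, "inpatient_day_cost",
                                      nbf_facility_levels),
        t2dm_expenditure_per_case = lv(uc, code, "t2dm_expenditure_per_case"),
        pct_t2dm_diagnosed = lv(uc, code, "pct_t2dm_diagnosed"),
        formula_price_per_900g = lv(uc, code, "formula_price_per_900g"),
        formula_containers_birth_to_24m =
          lv(uc, code, "formula_containers_birth_to_24m")))
  })
  names(profiles) <- codes
  profiles
}

#' Run configuration
#'
#' Bundles input/output locations, assumption overrides and the scenario
#' list for a pipeline run. Unknown keys are rejected. The effective config
#' is echoed into every output file for provenance.
#'
#' @param input_dir directory of long-format indicator CSVs.
#' @param output_dir where result files are written (NULL: no files).
#' @param discount_rate,gdp_growth,cognitive_exposure_mode,apply_wage_share,apply_lfpr
#'   assumption overrides (see \code{\link{nbf_assumptions}}).
#' @param grouping aggregation grouping for the main aggregate output.
#' @param scenarios character vector of scenario labels for sensitivity.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @param ... rejected; unknown keys are an error.
#' @return object of class \code{nbf_config}.
#' @export
nbf_config <- function(input_dir, output_dir = NULL,
                       discount_rate = 0.03, gdp_growth = 0.03,
                       cognitive_exposure_mode = "exclusive_lt6m",
                       apply_wage_share = FALSE, apply_lfpr = FALSE,
                       grouping = c("region", "income", "global"),
                       scenarios = c("default", "conservative", "optimistic"),
                       log_level = c("info", "quiet"), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 discount_rate = discount_rate, gdp_growth = gdp_growth,
                 cognitive_exposure_mode = cognitive_exposure_mode,
                 apply_wage_share = apply_wage_share, apply_lfpr = apply_lfpr,
                 grouping = match.arg(grouping),
                 scenarios = scenarios, log_level = match.arg(log_level)),
            class = "nbf_config")
}

config_echo <- function(config) {
  vals <- config[setdiff(names(config), NULL)]
  paste0("# config: ",
         paste(names(vals), vapply(vals, function(v)
           paste(format(v), collapse = "|"), character(1)),
           sep = "=", collapse = "; "))
}

write_with_echo <- function(df, path, echo) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(echo, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Reads the input directory, estimates every country (a failing country is
#' logged and skipped; the rest still run), aggregates, evaluates the
#' scenario grid, and -- when \code{output_dir} is set -- writes per-country
#' and aggregate CSVs plus a run log, each carrying the effective config
#' echo. Deterministic given inputs and config.
#'
#' @param config an \code{nbf_config}.
#' @return the \code{nbf_estimate} (invisibly when files are written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nbf_config"))
  profiles <- read_country_tables(config$input_dir)
  log_lines <- c(config_echo(config),
                 sprintf("countries read: %d", length(profiles)))
  ok <- rep(TRUE, length(profiles))
  for (i in seq_along(profiles)) {
    viol <- validate_profile(profiles[[i]])
    if (length(viol)) {
      ok[i] <- FALSE
      log_lines <- c(log_lines, sprintf("excluded %s: %s",
                                        profiles[[i]]$country_code,
                                        paste(viol, collapse = "; ")))
    }
  }
  profiles <- profiles[ok]
  if (!length(profiles)) stop("no valid country profiles to process")
  assumptions <- nbf_assumptions(
    discount_rate = config$discount_rate, gdp_growth = config$gdp_growth,
    cognitive_exposure_mode = config$cognitive_exposure_mode,
    apply_wage_share = config$apply_wage_share,
    apply_lfpr = config$apply_lfpr)
  fit <- nbf_estimate(profiles, assumptions,
                      scenarios = lapply(config$scenarios, nbf_scenario))
  for (r in fit$results)
    if (length(r$missing))
      log_lines <- c(log_lines, sprintf(
        "%s: component(s) not computed: %s (excluded from those sums)",
        r$country_code, paste(r$missing, collapse = ", ")))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    echo <- config_echo(config)
    out <- function(df, name)
      write_with_echo(df, file.path(config$output_dir, name), echo)
    out(fit$table, "countries.csv")
    out(as.data.frame(fit$by_region), "aggregate_region.csv")
    out(as.data.frame(fit$by_income), "aggregate_income.csv")
    out(as.data.frame(fit$global), "aggregate_global.csv")
    if (!is.null(fit$sensitivity)) out(fit$sensitivity, "sensitivity.csv")
    writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
    if (config$log_level == "info")
      message(sprintf("pipeline: %d countries -> %s", length(profiles),
                      config$output_dir))
    return(invisible(fit))
  }
  fit
}
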