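# Packaged published-table rows used as verification fixtures.

paper_table_md5 <- c(
  table1_morbidity.csv = "8d55a7d09de4ea9125dae5e805d93499",
  table2_mortality.csv = "de8a47800b00309bf0fd8438b435f786",
  table3_health_costs.csv = "dd944e783252579c4ba973e2c6bf47aa",
  table4_economic_losses.csv = "b5a4fee3fe81dff28807e02cdf377b0e")

#' Load the packaged published table rows
#'
#' Returns the regional, income-group and printed-total rows of the four
#' published summary tables (annual attributable morbidity, mortality,
#' health-system cost in US$ millions, and economic losses in US$ billions
#' with conservative/optimistic sensitivity bounds). Each data frame carries
#' a \code{grouping} column (\code{region}, \code{income},
#' \code{lmic_aggregate} for the combined low-and-middle-income row of the
#' losses table, \code{total} for the printed total row). Files are
#' checksum-verified on load.
#'
#' @return named list of data frames \code{morbidity}, \code{mortality},
#'   \code{health_costs}, \code{economic_losses}.
#' @export
load_paper_tables <- function() {
  dir <- system.file("extdata", package = "bfcost")
  files <- names(paper_table_md5)
  paths <- file.path(dir, files)
  sums <- tools::md5sum(paths)
  bad <- is.na(sums) | sums != paper_table_md5
  if (any(bad))
    stop("packaged table fixture failed checksum: ",
         paste(files[bad], collapse = ", "))
  tabs <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE)
  names(tabs) <- c("morbidity", "mortality", "health_costs", "economic_losses")
  tabs
}
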