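read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "vetamc", mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Published Fiji 2017-2021 annual class-by-year import quantities
#'
#' The year-by-class cells (kg of active ingredient) of the published
#' national veterinary antimicrobial import table for Fiji, 2017-2021,
#' bundled so the summary layer of the pipeline can be exercised without
#' access to the confidential record-level import database.
#'
#' @return `annual_class_totals` tibble (`year`, `class`, `subclass`, `kg`).
#' @export
fiji_annual_class_totals <- function() {
  annual_class_totals(read_fixture("fiji_annual_class_totals.csv"))
}

#' Published Fiji 2017-2021 annual import totals
#'
#' The published per-year totals (kg). These were computed by the source
#' from unrounded data, so they can differ from the sum of the rounded
#' published cells by ~0.01 kg; trend and mean/sd analyses of the annual
#' series use this table.
#'
#' @return tibble `year`, `total_kg`, ordered 2017-2021.
#' @export
fiji_annual_totals <- function() {
  read_fixture("fiji_annual_totals.csv")
}

#' Published Fiji 2017-2021 study-period class totals
#'
#' Cross-year class totals (kg) as printed in the published importance
#' summary; input for [classify_importance()].
#'
#' @return tibble `class`, `subclass`, `kg`.
#' @export
fiji_class_totals <- function() {
  read_fixture("fiji_class_totals.csv")
}
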