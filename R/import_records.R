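#' @importFrom rlang .data
NULL

#' Formulation kinds understood by the quantification rules
#' @export
FORMULATIONS <- c("LIQUID", "BLISTER", "IU_LIQUID")

record_columns <- c(
  "record_id", "year", "ingredient_name", "formulation", "strength",
  "container_volume_ml", "tablets_per_blister", "blisters_per_pack",
  "packs", "food_animal_indication"
)

#' Construct and validate a table of import records
#'
#' An import record is one shipment line of a finished veterinary product:
#' a liquid (strength in mg/ml plus container volume), a tablet blister
#' (strength in mg/tablet plus blister geometry), or an IU-denominated
#' liquid such as injectable penicillin G (strength in IU/ml). Formulation
#' geometry fields must be present exactly when the formulation requires
#' them and `NA` otherwise.
#'
#' @param df data frame with columns `record_id`, `year`, `ingredient_name`,
#'   `formulation`, `strength`, `container_volume_ml`, `tablets_per_blister`,
#'   `blisters_per_pack`, `packs`, `food_animal_indication`.
#' @param years optional integer vector; records outside this study window
#'   fail validation.
#' @return a validated tibble of class `amc_records`.
#' @export
amc_records <- function(df, years = NULL) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(record_columns, names(df))
  if (length(missing_cols) > 0) {
    abort_schema("missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), record_columns)
  if (length(extra) > 0) {
    rlang::warn(sprintf("ignoring unknown column(s): %s",
                        paste(extra, collapse = ", ")))
    df <- df[record_columns]
  }
  df$record_id <- as.character(df$record_id)
  df$year <- as.integer(df$year)
  df$ingredient_name <- as.character(df$ingredient_name)
  df$formulation <- as.character(df$formulation)
  df$packs <- as.integer(df$packs)
  df$food_animal_indication <- as.logical(df$food_animal_indication)

  if (nrow(df) == 0) {
    return(structure(df, class = c("amc_records", class(df))))
  }

  bad_rows <- function(cond) which(!is.na(cond) & cond)
  problems <- character()
  add <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("%s (rows %s)", what,
                                       paste(rows, collapse = ",")))
    }
  }

  add(which(!df$formulation %in% FORMULATIONS),
      "unknown formulation value")
  add(bad_rows(!is.finite(df$strength) | df$strength <= 0),
      "strength must be positive")
  add(bad_rows(df$packs < 1 | is.na(df$packs)), "packs must be >= 1")
  if (!is.null(years)) {
    add(bad_rows(!df$year %in% as.integer(years)),
        "year outside study window")
  }

  liquid <- df$formulation %in% c("LIQUID", "IU_LIQUID")
  blister <- df$formulation == "BLISTER"
  add(bad_rows(liquid & (is.na(df$container_volume_ml) |
                           df$container_volume_ml <= 0)),
      "liquid formulations need positive container_volume_ml")
  add(bad_rows(liquid & (!is.na(df$tablets_per_blister) |
                           !is.na(df$blisters_per_pack))),
      "liquid formulations must not carry blister geometry")
  add(bad_rows(blister & !is.na(df$container_volume_ml)),
      "blister formulations must not carry container_volume_ml")
  add(bad_rows(blister & (!is_count(df$tablets_per_blister) |
                            !is_count(df$blisters_per_pack))),
      "blister formulations need positive tablets_per_blister and blisters_per_pack")

  if (length(problems) > 0) {
    abort_schema("invalid import records:\n  %s",
                 paste(problems, collapse = "\n  "))
  }
  structure(df, class = c("amc_records", class(df)))
}

#' Read import records from CSV
#'
#' The CSV dialect is fixed (UTF-8, comma separator, `.` decimal) for
#' reproducibility across locales. Row numbers are preserved in
#' `record_id` when the file does not provide one.
#'
#' @param path path to a records CSV.
#' @param years optional study-window filter passed to [amc_records()].
#' @return tibble of class `amc_records`.
#' @export
read_import_records <- function(path, years = NULL) {
  if (!file.exists(path)) abort_schema("records file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        locale = readr::locale(decimal_mark = "."))
  if (!"record_id" %in% names(df) && nrow(df) > 0) {
    df$record_id <- sprintf("row%04d", seq_len(nrow(df)))
  }
  if (nrow(df) == 0) {
    df <- tibble::tibble(
      record_id = character(), year = integer(),
      ingredient_name = character(), formulation = character(),
      strength = double(), container_volume_ml = double(),
      tablets_per_blister = integer(), blisters_per_pack = integer(),
      packs = integer(), food_animal_indication = logical()
    )
  }
  amc_records(df, years = years)
}

#' Write import records to CSV
#'
#' Inverse of [read_import_records()]: writing then reading returns the
#' records field-for-field.
#'
#' @param records an `amc_records` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_import_records <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, progress = FALSE)
  invisible(path)
}

#' Drop records without a food-animal indication
#'
#' Import lines are screened for a recommendation for use in food animals
#' before any quantity enters downstream totals.
#'
#' @param records `amc_records`.
#' @return list with `kept` (records) and `excluded` (records), both
#'   `amc_records`.
#' @export
screen_food_animal <- function(records) {
  keep <- records$food_animal_indication %in% TRUE
  list(kept = amc_records(records[keep, , drop = FALSE]),
       excluded = amc_records(records[!keep, , drop = FALSE]))
}
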