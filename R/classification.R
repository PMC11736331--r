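class_woah_lookup <- function(totals, registry) {
  per_class <- registry$ingredients |>
    dplyr::distinct(.data$class, .data$woah, .data$who)
  conflicting <- per_class |>
    dplyr::count(.data$class) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicting) > 0) {
    # mixed WHO flags within a class resolve to the highest-priority one
    rank_who <- match(per_class$who, WHO_CATEGORIES)
    per_class <- per_class |>
      dplyr::mutate(.rank = rank_who) |>
      dplyr::group_by(.data$class, .data$woah) |>
      dplyr::slice_min(.data$.rank, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".rank")
  }
  missing <- setdiff(unique(totals$class), per_class$class)
  if (length(missing) > 0) {
    abort_resolution("class(es) absent from registry: %s",
                     paste(missing, collapse = ", "))
  }
  per_class
}

#' Partition class totals by WOAH veterinary importance
#'
#' Splits cross-year class totals into the WOAH categories VCIA
#' (veterinary critically important), VHIA (highly important) and VIA
#' (important). Classes outside the WOAH list (e.g. nitroimidazoles)
#' are reported separately as unclassified and excluded from the
#' classified grand total. All percentages are computed from unrounded
#' sums; the within-category share uses the category total, the
#' category share uses the classified total.
#'
#' @param totals `annual_class_totals`.
#' @param registry `amc_registry`.
#' @return object of class `importance_summary`: list with `classes`
#'   (tibble class, kg, woah, pct_of_category), `categories` (tibble
#'   woah, kg, pct_of_classified), `classified_kg`, `unclassified`
#'   (tibble class, kg).
#' @export
classify_importance <- function(totals, registry) {
  lookup <- class_woah_lookup(totals, registry)
  by_class <- class_totals(totals) |>
    dplyr::left_join(lookup, by = "class")

  classified <- by_class |> dplyr::filter(.data$woah != "UNCLASSIFIED")
  unclassified <- by_class |>
    dplyr::filter(.data$woah == "UNCLASSIFIED") |>
    dplyr::select("class", kg = "total_kg")
  classified_kg <- sum(classified$total_kg)

  classes <- classified |>
    dplyr::group_by(.data$woah) |>
    dplyr::mutate(pct_of_category = 100 * .data$total_kg /
                    sum(.data$total_kg)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$woah, WOAH_CATEGORIES),
                   dplyr::desc(.data$total_kg)) |>
    dplyr::select("class", kg = "total_kg", "woah", "who",
                  "pct_of_category")

  categories <- classes |>
    dplyr::group_by(.data$woah) |>
    dplyr::summarise(kg = sum(.data$kg), .groups = "drop") |>
    dplyr::mutate(pct_of_classified = 100 * .data$kg / classified_kg)

  structure(
    list(classes = classes, categories = categories,
         classified_kg = classified_kg, unclassified = unclassified),
    class = "importance_summary"
  )
}

#' Annotate an importance summary with WHO human-health flags
#'
#' Adds the WHO critically-important-antimicrobial footnote flags used in
#' published summary tables: highest-priority CIA (fluoroquinolones,
#' macrolides), high-priority CIA (aminoglycosides, penicillins). Classes
#' that are not WHO-critical (e.g. tetracyclines) carry no flag.
#'
#' @param summary `importance_summary` from [classify_importance()].
#' @return the summary with a `who_flag` column added to `$classes`
#'   (`"1"` = CIA highest priority, `"2"` = CIA high priority, `NA`
#'   otherwise).
#' @export
who_flags <- function(summary) {
  stopifnot(inherits(summary, "importance_summary"))
  summary$classes <- summary$classes |>
    dplyr::mutate(who_flag = dplyr::case_when(
      .data$who == "CIA_HIGHEST" ~ "1",
      .data$who == "CIA_HIGH" ~ "2",
      TRUE ~ NA_character_
    ))
  summary
}

#' Importance report table (published Table-2 layout)
#'
#' @param summary `importance_summary` (ideally after [who_flags()]).
#' @param digits report rounding.
#' @return tibble `class`, `woah`, `kg`, `pct_of_category`, `who_flag`.
#' @export
table2_report <- function(summary, digits = 2) {
  cl <- summary$classes
  if (!"who_flag" %in% names(cl)) cl$who_flag <- NA_character_
  cl |>
    dplyr::mutate(kg = round_half_up(.data$kg, digits),
                  pct_of_category = round_half_up(.data$pct_of_category,
                                                  digits)) |>
    dplyr::select("class", "woah", "kg", "pct_of_category", "who_flag")
}

#' @export
print.importance_summary <- function(x, ...) {
  cat("<importance_summary> classified total:",
      format(x$classified_kg), "kg\n")
  print(x$categories, ...)
  print(x$classes, ...)
  if (nrow(x$unclassified) > 0) {
    cat("unclassified (outside WOAH list):\n")
    print(x$unclassified, ...)
  }
  invisible(x)
}
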