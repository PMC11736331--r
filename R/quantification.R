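#' Active-ingredient mass in one container
#'
#' A liquid container (bottle, syringe) holding a formulation of strength
#' `s` mg/ml in a volume `v` ml contains `s * v / 1000` grams of active
#' ingredient.
#'
#' @param strength_mg_per_ml strength in mg/ml (> 0).
#' @param container_volume_ml container size in ml (> 0).
#' @return grams of active ingredient per container.
#' @export
container_amount_g <- function(strength_mg_per_ml, container_volume_ml) {
  if (!all(is.finite(strength_mg_per_ml)) || any(strength_mg_per_ml <= 0)) {
    abort_domain("strength must be finite and > 0")
  }
  if (!all(is.finite(container_volume_ml)) || any(container_volume_ml <= 0)) {
    abort_domain("container volume must be finite and > 0")
  }
  strength_mg_per_ml * container_volume_ml / 1000
}

#' Active-ingredient mass in one package of containers
#'
#' @param container_g grams per container (>= 0).
#' @param packs number of containers per shipment line (integer >= 1;
#'   typical pack counts are 4, 6, 10, 12 and 20, but single units occur).
#' @return grams of active ingredient in the package.
#' @export
package_amount_g <- function(container_g, packs) {
  if (any(container_g < 0) || !all(is.finite(container_g))) {
    abort_domain("container mass must be finite and >= 0")
  }
  if (!all(is_count(packs))) abort_domain("packs must be an integer >= 1")
  container_g * packs
}

#' Active-ingredient mass in one blister pack
#'
#' Tablet products: strength per tablet (mg) times number of blisters
#' times tablets per blister, over 1000 to give grams.
#'
#' @param strength_mg_per_tablet mg per tablet (> 0).
#' @param blisters blisters per pack (integer >= 1).
#' @param tablets_per_blister tablets per blister (integer >= 1).
#' @return grams of active ingredient per blister pack.
#' @export
blister_amount_g <- function(strength_mg_per_tablet, blisters,
                             tablets_per_blister) {
  if (!all(is.finite(strength_mg_per_tablet)) ||
      any(strength_mg_per_tablet <= 0)) {
    abort_domain("tablet strength must be finite and > 0")
  }
  if (!all(is_count(blisters)) || !all(is_count(tablets_per_blister))) {
    abort_domain("blister geometry must be integers >= 1")
  }
  strength_mg_per_tablet * blisters * tablets_per_blister / 1000
}

#' Convert an IU-denominated strength to mg/ml
#'
#' Potency-unit products (e.g. penicillin G for intramuscular injection)
#' declare strength in international units per ml; a compound-specific
#' factor (mg per IU) converts this to a mass strength that then feeds
#' [container_amount_g()].
#'
#' @param strength_iu_per_ml IU/ml (> 0).
#' @param iu_to_mg mg per IU (> 0).
#' @return strength in mg/ml.
#' @export
iu_to_mg_per_ml <- function(strength_iu_per_ml, iu_to_mg) {
  if (!all(is.finite(strength_iu_per_ml)) || any(strength_iu_per_ml <= 0)) {
    abort_domain("IU strength must be finite and > 0")
  }
  if (!all(is.finite(iu_to_mg)) || any(iu_to_mg <= 0)) {
    abort_domain("IU-to-mg factor must be finite and > 0")
  }
  strength_iu_per_ml * iu_to_mg
}

quantify_one <- function(formulation, strength, container_volume_ml,
                         tablets_per_blister, blisters_per_pack, packs,
                         iu_to_mg, ingredient_name) {
  switch(formulation,
    LIQUID = package_amount_g(
      container_amount_g(strength, container_volume_ml), packs),
    IU_LIQUID = {
      if (is.na(iu_to_mg)) {
        abort_resolution(
          "no IU-to-mg factor in registry for ingredient '%s'",
          ingredient_name)
      }
      package_amount_g(
        container_amount_g(iu_to_mg_per_ml(strength, iu_to_mg),
                           container_volume_ml),
        packs)
    },
    BLISTER = package_amount_g(
      blister_amount_g(strength, blisters_per_pack, tablets_per_blister),
      packs),
    abort_domain("unknown formulation '%s'", formulation)
  )
}

#' Quantify import records as grams of active ingredient
#'
#' Dispatches on formulation: liquids use strength x volume / 1000 then
#' x packs; IU liquids convert IU/ml to mg/ml first; blisters use
#' strength x blisters x tablets / 1000 then x packs. All arithmetic in
#' exact double-precision grams; rounding happens only at report time.
#'
#' @param records `amc_records` (already screened for food-animal use).
#' @param registry `amc_registry`.
#' @return tibble of class `amc_quantified`: `record_id`, `year`,
#'   `ingredient_name`, `canonical`, `class`, `subclass`, `grams_active`.
#' @export
quantify_records <- function(records, registry) {
  if (nrow(records) == 0) {
    out <- tibble::tibble(
      record_id = character(), year = integer(),
      ingredient_name = character(), canonical = character(),
      class = character(), subclass = character(),
      grams_active = double()
    )
    return(structure(out, class = c("amc_quantified", class(out))))
  }
  res <- resolve_ingredients(registry, records$ingredient_name)
  grams <- vapply(seq_len(nrow(records)), function(i) {
    quantify_one(records$formulation[i], records$strength[i],
                 records$container_volume_ml[i],
                 records$tablets_per_blister[i],
                 records$blisters_per_pack[i], records$packs[i],
                 res$iu_to_mg[i], records$ingredient_name[i])
  }, double(1))
  out <- tibble::tibble(
    record_id = records$record_id,
    year = records$year,
    ingredient_name = records$ingredient_name,
    canonical = res$canonical,
    class = res$class,
    subclass = res$subclass,
    grams_active = grams
  )
  structure(out, class = c("amc_quantified", class(out)))
}

#' Aggregate quantified imports to annual class totals
#'
#' Sums grams by (year, class, subclass) and converts to kilograms.
#' Conservation holds exactly: the grand total equals the sum of
#' record-level grams / 1000 (no intermediate rounding).
#'
#' @param quantified `amc_quantified` from [quantify_records()], or any
#'   tibble with `year`, `class`, `subclass`, and `grams_active` or `kg`.
#' @return tibble of class `annual_class_totals`: `year`, `class`,
#'   `subclass`, `kg`.
#' @export
aggregate_imports <- function(quantified) {
  if (nrow(quantified) == 0) {
    out <- tibble::tibble(year = integer(), class = character(),
                          subclass = character(), kg = double())
    return(structure(out, class = c("annual_class_totals", class(out))))
  }
  out <- quantified |>
    dplyr::group_by(.data$year, .data$class, .data$subclass) |>
    dplyr::summarise(kg = sum(.data$grams_active) / 1000, .groups = "drop") |>
    dplyr::arrange(.data$year, .data$class, .data$subclass)
  structure(out, class = c("annual_class_totals", class(out)))
}

#' Build an annual_class_totals table from already-summarised cells
#'
#' Entry point for summary-level data (e.g. published national tables
#' printed as kg per year and class) where record-level lines are not
#' available.
#'
#' @param df data frame with `year`, `class`, `kg` and optionally
#'   `subclass`.
#' @return `annual_class_totals` tibble.
#' @export
annual_class_totals <- function(df) {
  df <- tibble::as_tibble(df)
  need <- setdiff(c("year", "class", "kg"), names(df))
  if (length(need) > 0) {
    abort_schema("missing column(s): %s", paste(need, collapse = ", "))
  }
  if (!"subclass" %in% names(df)) df$subclass <- NA_character_
  if (any(!is.finite(df$kg)) || any(df$kg < 0)) {
    abort_domain("kg cells must be finite and >= 0")
  }
  df$year <- as.integer(df$year)
  out <- df[, c("year", "class", "subclass", "kg")]
  structure(out, class = c("annual_class_totals", class(out)))
}

#' Annual totals across classes
#' @param totals `annual_class_totals`.
#' @return tibble `year`, `total_kg`, ordered by year.
#' @export
annual_totals <- function(totals) {
  totals |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(total_kg = sum(.data$kg), .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Class totals across years
#' @param totals `annual_class_totals`.
#' @param by_subclass keep subclass rows separate (default collapses to
#'   parent class).
#' @return tibble `class` (and `subclass`), `total_kg`.
#' @export
class_totals <- function(totals, by_subclass = FALSE) {
  groups <- if (by_subclass) c("class", "subclass") else "class"
  totals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(total_kg = sum(.data$kg), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_kg))
}

#' Grand total of imported active ingredient
#' @param totals `annual_class_totals`.
#' @return total kilograms (unrounded sum of cells).
#' @export
grand_total <- function(totals) sum(totals$kg)

#' Year-by-class report table with percent-of-year shares
#'
#' Mirrors the layout of published national AMC tables: each cell is kg
#' with its share of the year column, percentages computed from unrounded
#' sums and rounded half-up at report time only.
#'
#' @param totals `annual_class_totals`.
#' @param digits report rounding (default 2).
#' @return tibble with one row per class/subclass per year plus share
#'   columns `kg`, `pct_of_year`.
#' @export
table1_report <- function(totals, digits = 2) {
  yr <- annual_totals(totals)
  totals |>
    dplyr::left_join(yr, by = "year") |>
    dplyr::mutate(
      pct_of_year = ifelse(.data$total_kg > 0,
                           100 * .data$kg / .data$total_kg, 0),
      kg = round_half_up(.data$kg, digits),
      pct_of_year = round_half_up(.data$pct_of_year, digits)
    ) |>
    dplyr::select("year", "class", "subclass", "kg", "pct_of_year")
}
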