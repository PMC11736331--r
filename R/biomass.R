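DEFAULT_COEFFICIENTS <- c(cattle = 0.7, sheep = 0.47, goat = 0.47,
                          pig = 0.78, chicken = 0.7)
SMALL_RUMINANT_WEIGHT_KG <- 37.5
DEFAULT_CHICKEN_WEIGHT_KG <- 2.0

#' Annual population growth rate between two censuses
#'
#' Compound annual growth rate implied by two census counts `y` years
#' apart: `r = (P2/P1)^(1/y) - 1`.
#'
#' @param P1 earlier census population (> 0).
#' @param P2 later census population (> 0).
#' @param y years between censuses (integer >= 1).
#' @return annual proportional growth rate `r` (negative for decline).
#' @export
growth_rate <- function(P1, P2, y) {
  if (any(!is.finite(P1)) || any(P1 <= 0) ||
      any(!is.finite(P2)) || any(P2 <= 0)) {
    abort_domain("census populations must be finite and > 0")
  }
  if (!all(is_count(y))) abort_domain("census interval y must be an integer >= 1")
  (P2 / P1)^(1 / y) - 1
}

#' Geometric population interpolation/extrapolation
#'
#' Projects a reference population forwards (`dt > 0`) or backwards
#' (`dt < 0`) at constant annual growth rate `r`. The result is a real
#' number, deliberately unrounded: the population enters biomass products
#' as a continuous denominator.
#'
#' @param P_ref reference population (> 0).
#' @param r annual growth rate from [growth_rate()].
#' @param dt signed offset in years from the reference.
#' @return interpolated population (real).
#' @export
interpolate_population <- function(P_ref, r, dt) {
  if (any(!is.finite(P_ref)) || any(P_ref <= 0)) {
    abort_domain("reference population must be finite and > 0")
  }
  P_ref * (1 + r)^dt
}

#' Mean carcass weight from slaughter statistics
#'
#' @param total_slaughter_weight_kg total weight of animals slaughtered (kg).
#' @param n_slaughtered number of animals slaughtered (integer >= 1).
#' @return kg per head. Zero total weight is allowed but flagged with a
#'   warning (degenerate reporting year).
#' @export
carcass_weight <- function(total_slaughter_weight_kg, n_slaughtered) {
  if (!all(is_count(n_slaughtered))) {
    abort_domain("number slaughtered must be an integer >= 1")
  }
  if (any(!is.finite(total_slaughter_weight_kg)) ||
      any(total_slaughter_weight_kg < 0)) {
    abort_domain("total slaughter weight must be finite and >= 0")
  }
  if (any(total_slaughter_weight_kg == 0)) {
    rlang::warn("zero total slaughter weight: carcass weight is 0 kg/head")
  }
  total_slaughter_weight_kg / n_slaughtered
}

#' Live weight from carcass weight
#'
#' Live weight = carcass weight / species conversion coefficient
#' (carcass-to-live-weight ratio; 0.7 cattle, 0.47 sheep and goats,
#' 0.78 pigs, 0.7 chicken). Since the coefficient is in (0, 1], live
#' weight is always >= carcass weight.
#'
#' @param carcass_kg carcass weight, kg/head.
#' @param conversion_coefficient ratio in (0, 1].
#' @return live weight, kg/head.
#' @export
live_weight <- function(carcass_kg, conversion_coefficient) {
  if (any(!is.finite(conversion_coefficient)) ||
      any(conversion_coefficient <= 0) || any(conversion_coefficient > 1)) {
    abort_domain("conversion coefficient must be in (0, 1]")
  }
  if (any(!is.finite(carcass_kg)) || any(carcass_kg < 0)) {
    abort_domain("carcass weight must be finite and >= 0")
  }
  carcass_kg / conversion_coefficient
}

#' Assemble denominator inputs for biomass estimation
#'
#' @param census tibble `species`, `year`, `population`: exactly two
#'   census points per species.
#' @param slaughter tibble `species`, `year`, `count`,
#'   `total_weight_kg` (may be empty for population-based species).
#' @param params optional tibble `species`, `conversion_coefficient`,
#'   `standard_weight_kg`; defaults cover cattle/sheep/goat/pig/chicken.
#' @return object of class `denominator_inputs`.
#' @export
denominator_inputs <- function(census, slaughter = NULL, params = NULL) {
  census <- tibble::as_tibble(census)
  need <- setdiff(c("species", "year", "population"), names(census))
  if (length(need) > 0) {
    abort_schema("census missing column(s): %s", paste(need, collapse = ", "))
  }
  if (any(census$population <= 0) || any(!is.finite(census$population))) {
    abort_domain("census populations must be finite and > 0")
  }
  per_sp <- table(census$species)
  if (any(per_sp != 2)) {
    abort_schema("each species needs exactly two census points; offending: %s",
                 paste(names(per_sp)[per_sp != 2], collapse = ", "))
  }
  dup <- census |>
    dplyr::count(.data$species, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort_schema("census years must be distinct per species")

  if (is.null(slaughter)) {
    slaughter <- tibble::tibble(species = character(), year = integer(),
                                count = double(), total_weight_kg = double())
  }
  slaughter <- tibble::as_tibble(slaughter)

  defaults <- tibble::tibble(
    species = names(DEFAULT_COEFFICIENTS),
    conversion_coefficient = unname(DEFAULT_COEFFICIENTS),
    standard_weight_kg = c(NA, SMALL_RUMINANT_WEIGHT_KG,
                           SMALL_RUMINANT_WEIGHT_KG, NA,
                           DEFAULT_CHICKEN_WEIGHT_KG)
  )
  if (!is.null(params)) {
    params <- tibble::as_tibble(params)
    defaults <- defaults |>
      dplyr::rows_update(params, by = "species", unmatched = "ignore")
  }
  if (any(defaults$conversion_coefficient <= 0 |
            defaults$conversion_coefficient > 1)) {
    abort_domain("conversion coefficients must be in (0, 1]")
  }
  structure(list(census = census, slaughter = slaughter, params = defaults),
            class = "denominator_inputs")
}

#' Read denominator inputs from a tidy CSV
#'
#' Schema: columns `species`, `field`, `year`, `value` with `field` one
#' of `census_pop`, `slaughter_count`, `slaughter_weight_kg`,
#' `conversion_coefficient`, `standard_weight_kg` (`year` empty for the
#' last two).
#'
#' @param path CSV path.
#' @return `denominator_inputs`.
#' @export
read_denominators <- function(path) {
  if (!file.exists(path)) abort_schema("denominators file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(c("species", "field", "year", "value"), names(df))
  if (length(need) > 0) {
    abort_schema("denominators missing column(s): %s",
                 paste(need, collapse = ", "))
  }
  census <- df |>
    dplyr::filter(.data$field == "census_pop") |>
    dplyr::transmute(species = .data$species, year = as.integer(.data$year),
                     population = .data$value)
  slaughter <- df |>
    dplyr::filter(.data$field %in% c("slaughter_count", "slaughter_weight_kg")) |>
    tidyr::pivot_wider(id_cols = c("species", "year"),
                       names_from = "field", values_from = "value") |>
    dplyr::transmute(species = .data$species, year = as.integer(.data$year),
                     count = .data$slaughter_count,
                     total_weight_kg = .data$slaughter_weight_kg)
  par_rows <- df |>
    dplyr::filter(.data$field %in% c("conversion_coefficient",
                                     "standard_weight_kg")) |>
    tidyr::pivot_wider(id_cols = "species", names_from = "field",
                       values_from = "value")
  params <- if (nrow(par_rows) > 0) par_rows else NULL
  denominator_inputs(census, slaughter, params)
}

species_growth <- function(inputs, species) {
  cs <- inputs$census[inputs$census$species == species, ]
  if (nrow(cs) != 2) abort_schema("no census pair for species '%s'", species)
  cs <- cs[order(cs$year), ]
  list(r = growth_rate(cs$population[1], cs$population[2],
                       cs$year[2] - cs$year[1]),
       ref_year = cs$year[2], ref_pop = cs$population[2])
}

species_population <- function(inputs, species, year) {
  g <- species_growth(inputs, species)
  interpolate_population(g$ref_pop, g$r, year - g$ref_year)
}

species_live_weight <- function(inputs, species, year) {
  par <- inputs$params[inputs$params$species == species, ]
  sl <- inputs$slaughter[inputs$slaughter$species == species &
                           inputs$slaughter$year == year, ]
  if (nrow(sl) == 1 && is.finite(sl$count) && sl$count >= 1 &&
      is.finite(sl$total_weight_kg)) {
    return(live_weight(carcass_weight(sl$total_weight_kg, sl$count),
                       par$conversion_coefficient))
  }
  if (nrow(par) == 1 && is.finite(par$standard_weight_kg)) {
    return(par$standard_weight_kg)
  }
  abort_domain("no slaughter data or standard weight for %s in %d",
               species, year)
}

#' Biomass of one species in one year
#'
#' Species conventions: cattle biomass is interpolated population x live
#' weight (slaughter proportions by age group being unavailable);
#' sheep and goats default to interpolated population x the 37.5 kg
#' small-ruminant standard weight (set `mode = "slaughter"` for the
#' slaughter-based alternative); pigs and chicken are number slaughtered
#' x live weight, with chicken falling back to a standard live weight
#' when slaughter statistics are missing.
#'
#' @param species one of cattle, sheep, goat, pig, chicken.
#' @param year calendar year.
#' @param inputs `denominator_inputs`.
#' @param mode small-ruminant basis: `"population"` (default) or
#'   `"slaughter"`.
#' @return biomass in kg.
#' @export
species_biomass <- function(species, year, inputs,
                            mode = c("population", "slaughter")) {
  mode <- match.arg(mode)
  stopifnot(inherits(inputs, "denominator_inputs"))
  par <- inputs$params[inputs$params$species == species, ]
  if (nrow(par) != 1) abort_schema("unknown species '%s'", species)

  if (species == "cattle") {
    return(species_population(inputs, species, year) *
             species_live_weight(inputs, species, year))
  }
  if (species %in% c("sheep", "goat") && mode == "population") {
    if (!is.finite(par$standard_weight_kg)) {
      abort_domain("no standard weight configured for %s", species)
    }
    return(species_population(inputs, species, year) * par$standard_weight_kg)
  }
  # slaughter-based species (pig, chicken; small ruminants in slaughter mode)
  sl <- inputs$slaughter[inputs$slaughter$species == species &
                           inputs$slaughter$year == year, ]
  if (nrow(sl) != 1 || !is.finite(sl$count)) {
    if (species == "chicken" && is.finite(par$standard_weight_kg)) {
      # no slaughter statistics: population-based fallback
      return(species_population(inputs, species, year) *
               par$standard_weight_kg)
    }
    abort_domain("missing slaughter data for %s in %d", species, year)
  }
  sl$count * species_live_weight(inputs, species, year)
}

#' National food-animal biomass for one or more years
#'
#' @param years integer vector of calendar years.
#' @param inputs `denominator_inputs`.
#' @param mode see [species_biomass()].
#' @return tibble `year`, `biomass_kg` (sum over all configured species).
#' @export
national_biomass <- function(years, inputs,
                             mode = c("population", "slaughter")) {
  mode <- match.arg(mode)
  species <- inputs$params$species
  tibble::tibble(
    year = as.integer(years),
    biomass_kg = vapply(years, function(y) {
      sum(vapply(species, species_biomass, double(1), year = y,
                 inputs = inputs, mode = mode))
    }, double(1))
  )
}

#' Species-by-year biomass table
#'
#' @inheritParams national_biomass
#' @return tibble `species`, `year`, `biomass_kg`.
#' @export
biomass_table <- function(years, inputs,
                          mode = c("population", "slaughter")) {
  mode <- match.arg(mode)
  grid <- expand.grid(species = inputs$params$species,
                      year = as.integer(years),
                      stringsAsFactors = FALSE)
  grid$biomass_kg <- mapply(function(s, y) {
    species_biomass(s, y, inputs, mode = mode)
  }, grid$species, grid$year)
  tibble::as_tibble(grid)
}
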