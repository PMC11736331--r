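DEFAULT_CLASS_MIX <- c(
  Penicillins = 0.55, Tetracyclines = 0.20, Sulfonamides = 0.08,
  Macrolides = 0.05, Lincosamides = 0.04, Cephalosporins = 0.04,
  Aminoglycosides = 0.02, Quinolones = 0.01, Nitroimidazoles = 0.01
)
DEFAULT_FORMULATION_MIX <- c(LIQUID = 0.7, BLISTER = 0.2, IU_LIQUID = 0.1)

#' Configuration for the synthetic import-data generator
#'
#' The generator emulates a tier-1 national import register: right-skewed
#' per-shipment quantities (log-normal), a class mix dominated by
#' penicillins and tetracyclines as observed in Pacific import data, a
#' mixture of liquid, blister and IU-denominated formulations, and
#' optional per-year shock multipliers emulating an import collapse such
#' as the 2020-2021 pandemic disruption.
#'
#' @param seed integer RNG seed; one RNG stream per generator call.
#' @param years study years.
#' @param n_per_year records per year (scalar or per-year vector).
#' @param class_mix named probabilities over antimicrobial classes
#'   (must sum to 1).
#' @param formulation_mix named probabilities over LIQUID / BLISTER /
#'   IU_LIQUID (must sum to 1).
#' @param meanlog,sdlog log-normal parameters of per-record grams of
#'   active ingredient.
#' @param shock_years named multipliers (names = years) applied to the
#'   drawn per-record mass.
#' @return validated list of class `amc_sim_config`.
#' @export
amc_sim_config <- function(seed = 1L, years = 2017:2021, n_per_year = 100,
                           class_mix = DEFAULT_CLASS_MIX,
                           formulation_mix = DEFAULT_FORMULATION_MIX,
                           meanlog = 6, sdlog = 1.3,
                           shock_years = c("2020" = 0.15, "2021" = 0.2)) {
  stopifnot(length(years) >= 1, all(is.finite(years)))
  if (length(n_per_year) == 1) {
    n_per_year <- rep(n_per_year, length(years))
  }
  if (length(n_per_year) != length(years)) {
    abort_domain("n_per_year must be scalar or one value per year")
  }
  n_per_year <- stats::setNames(as.integer(n_per_year),
                                as.character(years))
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    abort_domain("class_mix must be non-negative and sum to 1")
  }
  if (any(formulation_mix < 0) || abs(sum(formulation_mix) - 1) > 1e-9) {
    abort_domain("formulation_mix must be non-negative and sum to 1")
  }
  if (!all(names(formulation_mix) %in% FORMULATIONS)) {
    abort_domain("formulation_mix names must be in %s",
                 paste(FORMULATIONS, collapse = "/"))
  }
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 n_per_year = n_per_year, class_mix = class_mix,
                 formulation_mix = formulation_mix, meanlog = meanlog,
                 sdlog = sdlog, shock_years = shock_years),
            class = "amc_sim_config")
}

PACK_GRID <- c(1L, 4L, 6L, 10L, 12L, 20L)
LIQUID_STRENGTH_GRID <- c(50, 100, 150, 200, 250, 300)      # mg/ml
TABLET_STRENGTH_GRID <- c(100, 250, 500)                    # mg/tablet
TABLETS_GRID <- c(8L, 10L, 12L)
IU_STRENGTH_GRID <- c(2e5, 3e5, 4e5)                        # IU/ml

solve_geometry <- function(target_g, formulation, iu_factor,
                           max_retries = 25) {
  for (try in seq_len(max_retries)) {
    packs <- sample(PACK_GRID, 1)
    if (formulation == "LIQUID") {
      strength <- sample(LIQUID_STRENGTH_GRID, 1)
      volume <- target_g * 1000 / (strength * packs)
      if (volume >= 0.5 && volume <= 5e4) {
        return(list(strength = strength, container_volume_ml = volume,
                    tablets_per_blister = NA_integer_,
                    blisters_per_pack = NA_integer_, packs = packs))
      }
    } else if (formulation == "IU_LIQUID") {
      strength <- sample(IU_STRENGTH_GRID, 1)
      mg_ml <- strength * iu_factor
      volume <- target_g * 1000 / (mg_ml * packs)
      if (volume >= 0.5 && volume <= 5e4) {
        return(list(strength = strength, container_volume_ml = volume,
                    tablets_per_blister = NA_integer_,
                    blisters_per_pack = NA_integer_, packs = packs))
      }
    } else {
      strength <- sample(TABLET_STRENGTH_GRID, 1)
      tablets <- sample(TABLETS_GRID, 1)
      blisters <- round(target_g * 1000 / (strength * tablets * packs))
      if (blisters >= 1 && blisters <= 1e4) {
        return(list(strength = strength,
                    container_volume_ml = NA_real_,
                    tablets_per_blister = tablets,
                    blisters_per_pack = as.integer(blisters),
                    packs = packs))
      }
    }
  }
  abort_domain("no feasible %s geometry for a drawn mass of %.3f g",
               formulation, target_g)
}

# grams implied by a solved geometry, same operation order as quantify_one
implied_grams <- function(geom, formulation, iu_factor) {
  if (formulation == "LIQUID") {
    (geom$strength * geom$container_volume_ml / 1000) * geom$packs
  } else if (formulation == "IU_LIQUID") {
    ((geom$strength * iu_factor) * geom$container_volume_ml / 1000) *
      geom$packs
  } else {
    (geom$strength * geom$blisters_per_pack * geom$tablets_per_blister /
       1000) * geom$packs
  }
}

#' Generate synthetic import records with an exact ground-truth ledger
#'
#' Per-record target masses are drawn log-normally, then back-solved into
#' valid formulation geometry (strength, volume, pack and blister counts
#' from realistic grids) so that the quantification equations reproduce
#' each record's grams exactly. The returned ledger holds the exact
#' (year, class) gram sums, making `aggregate(quantify(records))` testable
#' against known truth with zero tolerance.
#'
#' @param config `amc_sim_config`.
#' @param registry `amc_registry`; ingredients are drawn per class from it.
#' @return list with `records` (`amc_records`) and `ledger` (tibble
#'   `year`, `class`, `subclass`, `grams`).
#' @export
generate_records <- function(config, registry = load_registry()) {
  stopifnot(inherits(config, "amc_sim_config"))
  set.seed(config$seed)

  n_total <- sum(config$n_per_year)
  if (n_total == 0) {
    records <- amc_records(tibble::tibble(
      record_id = character(), year = integer(),
      ingredient_name = character(), formulation = character(),
      strength = double(), container_volume_ml = double(),
      tablets_per_blister = integer(), blisters_per_pack = integer(),
      packs = integer(), food_animal_indication = logical()
    ))
    ledger <- tibble::tibble(year = integer(), class = character(),
                             subclass = character(), grams = double())
    return(list(records = records, ledger = ledger))
  }

  classes <- names(config$class_mix)
  absent <- setdiff(classes[config$class_mix > 0],
                    registry$ingredients$class)
  if (length(absent) > 0) {
    abort_resolution("class_mix class(es) missing from registry: %s",
                     paste(absent, collapse = ", "))
  }

  rows <- vector("list", n_total)
  k <- 0
  for (yi in seq_along(config$years)) {
    year <- config$years[yi]
    shock <- config$shock_years[as.character(year)]
    if (is.na(shock)) shock <- 1
    for (i in seq_len(config$n_per_year[[as.character(year)]])) {
      k <- k + 1
      cls <- sample(classes, 1, prob = config$class_mix)
      members <- registry$ingredients[registry$ingredients$class == cls, ]
      ing <- members[sample(nrow(members), 1), ]
      formulation <- sample(names(config$formulation_mix), 1,
                            prob = config$formulation_mix)
      if (formulation == "IU_LIQUID" && is.na(ing$iu_to_mg)) {
        formulation <- "LIQUID"   # IU denominations only exist for
      }                           # potency-unit ingredients
      target_g <- stats::rlnorm(1, config$meanlog, config$sdlog) * shock
      geom <- solve_geometry(target_g, formulation, ing$iu_to_mg)
      rows[[k]] <- tibble::tibble(
        record_id = sprintf("sim%05d", k),
        year = year,
        ingredient_name = ing$name,
        formulation = formulation,
        strength = geom$strength,
        container_volume_ml = geom$container_volume_ml,
        tablets_per_blister = geom$tablets_per_blister,
        blisters_per_pack = geom$blisters_per_pack,
        packs = geom$packs,
        food_animal_indication = TRUE,
        class = ing$class,
        subclass = ing$subclass,
        grams = implied_grams(geom, formulation, ing$iu_to_mg)
      )
    }
  }
  all_rows <- dplyr::bind_rows(rows)
  ledger <- all_rows |>
    dplyr::group_by(.data$year, .data$class, .data$subclass) |>
    dplyr::summarise(grams = sum(.data$grams), .groups = "drop") |>
    dplyr::arrange(.data$year, .data$class, .data$subclass)
  records <- amc_records(all_rows[record_columns])
  list(records = records, ledger = ledger)
}

#' Generate synthetic denominator inputs with a known biomass ledger
#'
#' Draws per-species compound annual growth, census pairs consistent with
#' it, and slaughter statistics consistent with drawn carcass weights,
#' then records the implied exact national biomass per year in a ledger.
#' Population scales emulate a small Pacific island livestock sector.
#'
#' @param config `amc_sim_config` (uses `seed` + 1 for an independent
#'   stream and the study `years`).
#' @return list with `inputs` (`denominator_inputs`) and `ledger`
#'   (tibble `year`, `biomass_kg`).
#' @export
generate_denominators <- function(config) {
  stopifnot(inherits(config, "amc_sim_config"))
  set.seed(config$seed + 1L)
  years <- config$years
  census_y1 <- 2009L
  census_y2 <- 2020L
  gap <- census_y2 - census_y1

  base_pop <- c(cattle = 120000, sheep = 37000, goat = 144000,
                pig = 100000, chicken = 1400000)
  carcass_mean <- c(cattle = 160, pig = 70, chicken = 1.4)
  slaughter_n <- c(cattle = 8000, pig = 30000, chicken = 1e6)

  species <- names(base_pop)
  r_drawn <- stats::runif(length(species), -0.03, 0.05)
  names(r_drawn) <- species
  P2 <- round(base_pop * stats::runif(length(species), 0.8, 1.2))
  P1 <- pmax(1, round(P2 / (1 + r_drawn)^gap))

  census_years <- rep(c(census_y1, census_y2), length(species))
  census <- tibble::tibble(
    species = rep(species, each = 2),
    year = census_years,
    population = as.vector(rbind(P1, P2))
  )

  sl_species <- names(carcass_mean)
  slaughter <- dplyr::bind_rows(lapply(sl_species, function(sp) {
    n <- round(slaughter_n[[sp]] * stats::runif(length(years), 0.85, 1.15))
    cw <- carcass_mean[[sp]] * stats::runif(length(years), 0.9, 1.1)
    tibble::tibble(species = sp, year = as.integer(years), count = n,
                   total_weight_kg = n * cw)
  }))

  inputs <- denominator_inputs(census, slaughter)

  # ledger: implied biomass per year, same formulas applied independently
  coef <- DEFAULT_COEFFICIENTS
  ledger <- tibble::tibble(year = as.integer(years))
  ledger$biomass_kg <- vapply(years, function(y) {
    total <- 0
    for (sp in species) {
      p1 <- census$population[census$species == sp &
                                census$year == census_y1]
      p2 <- census$population[census$species == sp &
                                census$year == census_y2]
      r <- (p2 / p1)^(1 / gap) - 1
      pop <- p2 * (1 + r)^(y - census_y2)
      if (sp == "cattle") {
        sl <- slaughter[slaughter$species == sp & slaughter$year == y, ]
        lw <- (sl$total_weight_kg / sl$count) / coef[[sp]]
        total <- total + pop * lw
      } else if (sp %in% c("sheep", "goat")) {
        total <- total + pop * SMALL_RUMINANT_WEIGHT_KG
      } else {
        sl <- slaughter[slaughter$species == sp & slaughter$year == y, ]
        lw <- (sl$total_weight_kg / sl$count) / coef[[sp]]
        total <- total + sl$count * lw
      }
    }
    total
  }, double(1))

  list(inputs = inputs, ledger = ledger)
}

#' Write a synthetic dataset to disk
#'
#' Convenience wrapper producing `records.csv`, `denominators.csv` and
#' `ledger.json` in an output directory.
#'
#' @param config `amc_sim_config`.
#' @param out_dir output directory (created if needed).
#' @param registry `amc_registry`.
#' @return invisible list of written paths.
#' @export
simulate_dataset <- function(config, out_dir, registry = load_registry()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- generate_records(config, registry)
  den <- generate_denominators(config)

  records_path <- file.path(out_dir, "records.csv")
  write_import_records(rec$records, records_path)

  den_long <- dplyr::bind_rows(
    den$inputs$census |>
      dplyr::transmute(species = .data$species, field = "census_pop",
                       year = .data$year, value = .data$population),
    den$inputs$slaughter |>
      dplyr::transmute(species = .data$species, field = "slaughter_count",
                       year = .data$year, value = .data$count),
    den$inputs$slaughter |>
      dplyr::transmute(species = .data$species,
                       field = "slaughter_weight_kg",
                       year = .data$year, value = .data$total_weight_kg)
  )
  denom_path <- file.path(out_dir, "denominators.csv")
  readr::write_csv(den_long, denom_path, progress = FALSE)

  ledger_path <- file.path(out_dir, "ledger.json")
  jsonlite::write_json(
    list(records = rec$ledger, biomass = den$ledger),
    ledger_path, dataframe = "rows", digits = NA
  )
  invisible(list(records = records_path, denominators = denom_path,
                 ledger = ledger_path))
}
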