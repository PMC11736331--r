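WOAH_CATEGORIES <- c("VCIA", "VHIA", "VIA", "UNCLASSIFIED")
WHO_CATEGORIES <- c("CIA_HIGHEST", "CIA_HIGH", "HIGHLY_IMPORTANT",
                    "IMPORTANT", "UNCLASSIFIED")

#' Path to the bundled ingredient registry
#' @return path to the package's default `registry.yaml`.
#' @export
default_registry_path <- function() {
  system.file("extdata", "registry.yaml", package = "vetamc",
              mustWork = TRUE)
}

#' Load an antimicrobial ingredient registry
#'
#' The registry maps each active-ingredient name (after case folding and
#' salt-synonym normalisation, e.g. "tetracycline hydrochloride" ->
#' "tetracycline") to its antimicrobial class, optional subclass, WOAH
#' veterinary-importance category, WHO human-health-importance category,
#' and — for IU-denominated products — an IU-to-mg conversion factor.
#'
#' @param path YAML registry file; defaults to the bundled registry
#'   covering the ingredients recorded in the Fiji 2017-2021 import data.
#' @return an object of class `amc_registry`: list with `ingredients`
#'   (tibble), `synonyms` (named character), `list_edition` (list).
#' @export
load_registry <- function(path = default_registry_path()) {
  if (!file.exists(path)) abort_schema("registry file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$ingredients)) abort_schema("registry has no ingredients block")

  ing <- dplyr::bind_rows(lapply(raw$ingredients, function(x) {
    tibble::tibble(
      name = tolower(x$name),
      class = x$class,
      subclass = x$subclass %||% NA_character_,
      woah = x$woah %||% "UNCLASSIFIED",
      who = x$who %||% "UNCLASSIFIED",
      iu_to_mg = x$iu_to_mg %||% NA_real_
    )
  }))
  if (anyDuplicated(ing$name)) {
    abort_schema("duplicate ingredient name(s): %s",
                 paste(unique(ing$name[duplicated(ing$name)]), collapse = ", "))
  }
  bad_woah <- setdiff(unique(ing$woah), WOAH_CATEGORIES)
  if (length(bad_woah) > 0) {
    abort_schema("unknown WOAH category: %s", paste(bad_woah, collapse = ", "))
  }
  bad_who <- setdiff(unique(ing$who), WHO_CATEGORIES)
  if (length(bad_who) > 0) {
    abort_schema("unknown WHO category: %s", paste(bad_who, collapse = ", "))
  }
  if (any(!is.na(ing$iu_to_mg) & ing$iu_to_mg < 0)) {
    abort_schema("iu_to_mg factors must be non-negative")
  }

  synonyms <- unlist(raw$synonyms %||% list())
  if (length(synonyms) > 0) {
    names(synonyms) <- tolower(names(synonyms))
    synonyms <- vapply(synonyms, tolower, character(1))
    orphan <- setdiff(unique(synonyms), ing$name)
    if (length(orphan) > 0) {
      abort_schema("synonym target(s) missing from ingredients: %s",
                   paste(orphan, collapse = ", "))
    }
  }

  structure(
    list(ingredients = ing, synonyms = synonyms,
         list_edition = raw$list_edition %||% list()),
    class = "amc_registry"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise an ingredient name to its registry canonical form
#'
#' Lowercases and applies the registry's salt-synonym table.
#'
#' @param registry `amc_registry`.
#' @param name character vector of declared compound names.
#' @return canonical names (may be absent from the registry; see
#'   [resolve_ingredients()]).
#' @export
normalise_ingredient <- function(registry, name) {
  key <- tolower(trimws(name))
  hit <- match(key, names(registry$synonyms))
  key[!is.na(hit)] <- unname(registry$synonyms[hit[!is.na(hit)]])
  key
}

#' Resolve declared ingredient names against the registry
#'
#' @param registry `amc_registry`.
#' @param name character vector of declared names.
#' @return tibble with one row per input: `name`, `canonical`, `class`,
#'   `subclass`, `woah`, `who`, `iu_to_mg`. Errors (does not silently
#'   drop) if any name fails to resolve.
#' @export
resolve_ingredients <- function(registry, name) {
  canonical <- normalise_ingredient(registry, name)
  idx <- match(canonical, registry$ingredients$name)
  if (anyNA(idx)) {
    abort_resolution("ingredient(s) not in registry: %s",
                     paste(unique(name[is.na(idx)]), collapse = ", "))
  }
  dplyr::bind_cols(
    tibble::tibble(name = name, canonical = canonical),
    registry$ingredients[idx, c("class", "subclass", "woah", "who", "iu_to_mg")]
  )
}

#' @export
print.amc_registry <- function(x, ...) {
  cat("<amc_registry> ", nrow(x$ingredients), " ingredients, ",
      length(x$synonyms), " synonyms\n", sep = "")
  print(x$ingredients, ...)
  invisible(x)
}
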