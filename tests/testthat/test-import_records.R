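test_that("record CSV round-trips field-for-field", {
  recs <- tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_import_records(recs, path)
  back <- read_import_records(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(recs))
})

test_that("empty CSV with valid header gives an empty record set", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(
    "record_id,year,ingredient_name,formulation,strength,container_volume_ml",
    "tablets_per_blister,blisters_per_pack,packs,food_animal_indication",
    sep = ","), path)
  recs <- read_import_records(path)
  expect_s3_class(recs, "amc_records")
  expect_equal(nrow(recs), 0)
})

test_that("formulation-specific field invariants are enforced", {
  base <- tibble::as_tibble(tiny_records())
  # blister row carrying a container volume
  bad <- base
  bad$container_volume_ml[3] <- 100
  expect_error(amc_records(bad), class = "vetamc_schema_error")
  # liquid row missing its volume
  bad <- base
  bad$container_volume_ml[1] <- NA
  expect_error(amc_records(bad), class = "vetamc_schema_error")
  # negative strength names the offending constraint
  bad <- base
  bad$strength[2] <- -5
  expect_error(amc_records(bad), "strength", class = "vetamc_schema_error")
  # zero packs
  bad <- base
  bad$packs[1] <- 0L
  expect_error(amc_records(bad), "packs", class = "vetamc_schema_error")
  # unknown formulation never guesses a default
  bad <- base
  bad$formulation[1] <- "POWDER"
  expect_error(amc_records(bad), "formulation", class = "vetamc_schema_error")
})

test_that("missing required columns and study-window violations are schema errors", {
  base <- tibble::as_tibble(tiny_records())
  expect_error(amc_records(base[, -2]), "year", class = "vetamc_schema_error")
  expect_error(amc_records(base, years = 2019:2021),
               "study window", class = "vetamc_schema_error")
  expect_silent(amc_records(base, years = 2017:2021))
})

test_that("unknown columns are ignored with a warning", {
  base <- tibble::as_tibble(tiny_records())
  base$importer <- "x"
  expect_warning(recs <- amc_records(base), "importer")
  expect_false("importer" %in% names(recs))
})

test_that("records without food-animal indication are screened out", {
  base <- tibble::as_tibble(tiny_records())
  base$food_animal_indication[2] <- FALSE
  sc <- screen_food_animal(amc_records(base))
  expect_equal(nrow(sc$kept), 2)
  expect_equal(sc$excluded$record_id, "b")
})

test_that("bundled registry resolves declared salt names to classes and categories", {
  reg <- load_registry()
  res <- resolve_ingredients(reg, c("penicillin G procaine",
                                    "lincomycin hydrochloride monohydrate",
                                    "Tetracycline Hydrochloride"))
  expect_equal(res$class, c("Penicillins", "Lincosamides", "Tetracyclines"))
  expect_equal(res$woah, c("VCIA", "VHIA", "VCIA"))
  expect_equal(res$who[1], "CIA_HIGH")
  expect_equal(res$iu_to_mg[1], 6e-4)
})

test_that("unresolvable ingredients raise a resolution error naming them", {
  reg <- load_registry()
  expect_error(resolve_ingredients(reg, "colistin sulfate"),
               "colistin", class = "vetamc_resolution_error")
})

test_that("registry validation rejects duplicates and bad categories", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "ingredients:",
    "  - name: ampicillin",
    "    class: Penicillins",
    "    woah: VCIA",
    "  - name: ampicillin",
    "    class: Penicillins",
    "    woah: VCIA"), path)
  expect_error(load_registry(path), "duplicate",
               class = "vetamc_schema_error")
  writeLines(c(
    "ingredients:",
    "  - name: ampicillin",
    "    class: Penicillins",
    "    woah: SUPER_IMPORTANT"), path)
  expect_error(load_registry(path), "WOAH", class = "vetamc_schema_error")
})
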