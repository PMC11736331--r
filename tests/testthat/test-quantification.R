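test_that("container, package and blister masses follow the conversion rules", {
  expect_equal(container_amount_g(200, 100), 20)
  expect_equal(container_amount_g(1, 1000), 1)
  expect_equal(container_amount_g(150, 250), 37.5)   # mg/ml x ml -> mg -> g

  expect_equal(package_amount_g(20, 1), 20)
  expect_equal(package_amount_g(20, 12), 240)
  # oracle: repeated addition
  expect_equal(package_amount_g(37.5, 6), sum(rep(37.5, 6)))

  expect_equal(blister_amount_g(500, 6, 10), 30)
  expect_equal(blister_amount_g(250, 1, 1), 0.25)
  # oracle: per-tablet summation
  expect_equal(blister_amount_g(100, 12, 8), sum(rep(100, 12 * 8)) / 1000)
})

test_that("domain errors reject non-positive geometry", {
  expect_error(container_amount_g(0, 100), class = "vetamc_domain_error")
  expect_error(container_amount_g(200, -1), class = "vetamc_domain_error")
  expect_error(package_amount_g(20, 0), class = "vetamc_domain_error")
  expect_error(blister_amount_g(500, 0, 10), class = "vetamc_domain_error")
  expect_error(iu_to_mg_per_ml(0, 6e-4), class = "vetamc_domain_error")
})

test_that("IU strengths convert to mg/ml via the registry factor", {
  expect_equal(iu_to_mg_per_ml(3e5, 6e-4), 180)
  expect_equal(iu_to_mg_per_ml(1, 1), 1)
})

test_that("quantify_records dispatches on formulation", {
  reg <- load_registry()
  q <- quantify_records(tiny_records(), reg)
  # LIQUID 200 mg/ml x 100 ml x 12 packs; LIQUID 100 x 50 x 1; BLISTER 500x10x6
  expect_equal(q$grams_active, c(240, 5, 30))
  expect_equal(q$class, c("Penicillins", "Tetracyclines", "Macrolides"))

  iu_rec <- amc_records(tibble::tibble(
    record_id = "iu1", year = 2019L,
    ingredient_name = "penicillin G procaine", formulation = "IU_LIQUID",
    strength = 3e5, container_volume_ml = 10,
    tablets_per_blister = NA_integer_, blisters_per_pack = NA_integer_,
    packs = 4L, food_animal_indication = TRUE
  ))
  expect_equal(quantify_records(iu_rec, reg)$grams_active, 7.2)
})

test_that("an IU record for an ingredient without a factor is a resolution error", {
  reg <- load_registry()
  rec <- amc_records(tibble::tibble(
    record_id = "x", year = 2019L, ingredient_name = "erythromycin",
    formulation = "IU_LIQUID", strength = 1e5, container_volume_ml = 10,
    tablets_per_blister = NA_integer_, blisters_per_pack = NA_integer_,
    packs = 1L, food_animal_indication = TRUE
  ))
  expect_error(quantify_records(rec, reg), "erythromycin",
               class = "vetamc_resolution_error")
})

test_that("quantification is linear in packs and strength", {
  reg <- load_registry()
  base <- tibble::as_tibble(tiny_records())[1, ]
  for (mult in c(2L, 5L)) {
    scaled <- base
    scaled$packs <- base$packs * mult
    expect_equal(quantify_records(amc_records(scaled), reg)$grams_active,
                 mult * quantify_records(amc_records(base), reg)$grams_active)
    scaled <- base
    scaled$strength <- base$strength * mult
    expect_equal(quantify_records(amc_records(scaled), reg)$grams_active,
                 mult * quantify_records(amc_records(base), reg)$grams_active)
  }
})

test_that("aggregation conserves mass and ignores record order", {
  reg <- load_registry()
  set.seed(42)
  sim <- generate_records(amc_sim_config(seed = 42, n_per_year = 20))
  q <- quantify_records(sim$records, reg)
  agg <- aggregate_imports(q)
  expect_equal(grand_total(agg), sum(q$grams_active) / 1000,
               tolerance = 1e-9)
  # permutation invariance
  q_shuffled <- q[sample(nrow(q)), ]
  agg2 <- aggregate_imports(q_shuffled)
  expect_equal(dplyr::arrange(tibble::as_tibble(agg2), year, class, subclass),
               dplyr::arrange(tibble::as_tibble(agg), year, class, subclass),
               tolerance = 1e-12)
})

test_that("aggregate handles empty input and same-cell additivity", {
  empty <- quantify_records(
    amc_records(tibble::as_tibble(tiny_records())[0, ]), load_registry())
  agg <- aggregate_imports(empty)
  expect_equal(nrow(agg), 0)
  expect_equal(grand_total(agg), 0)

  two <- tibble::tibble(
    record_id = c("a", "b"), year = 2020L, ingredient_name = "tetracycline",
    canonical = "tetracycline", class = "Tetracyclines",
    subclass = NA_character_, grams_active = c(100, 150))
  agg2 <- aggregate_imports(two)
  expect_equal(nrow(agg2), 1)
  expect_equal(agg2$kg, 0.25)
})

test_that("report table percentages sum to 100 within each year", {
  cells <- fiji_annual_class_totals()
  rep1 <- table1_report(cells)
  sums <- rep1 |>
    dplyr::group_by(year) |>
    dplyr::summarise(p = sum(pct_of_year))
  expect_true(all(abs(sums$p - 100) < 0.05))  # report-time rounding only
})
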