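test_that("growth rate matches its defining compound-growth identity", {
  expect_equal(growth_rate(1000, 1000, 11), 0)
  r <- growth_rate(100, 200, 11)
  expect_equal(r, 0.06504, tolerance = 1e-4)
  expect_equal(100 * (1 + r)^11, 200, tolerance = 1e-9)   # oracle
  r_down <- growth_rate(200, 100, 11)
  expect_equal(r_down, -0.06107, tolerance = 1e-4)
  expect_equal(200 * (1 + r_down)^11, 100, tolerance = 1e-9)
  expect_error(growth_rate(0, 100, 11), class = "vetamc_domain_error")
})

test_that("growth_rate and interpolate_population are mutual inverses", {
  set.seed(7)
  for (i in 1:50) {
    P1 <- runif(1, 1e3, 1e6)
    P2 <- runif(1, 1e3, 1e6)
    y <- sample(1:20, 1)
    r <- growth_rate(P1, P2, y)
    expect_equal(interpolate_population(P1, r, y), P2,
                 tolerance = 1e-9)
    expect_equal(interpolate_population(P2, r, -y), P1,
                 tolerance = 1e-9)
  }
  expect_equal(interpolate_population(119691, 0, 1), 119691)
  expect_equal(interpolate_population(100, 0.06504, 11), 200,
               tolerance = 1e-4)
})

test_that("carcass and live weights follow the slaughter conventions", {
  expect_equal(carcass_weight(210000, 1000), 210)
  expect_equal(carcass_weight(37500, 500), 75)
  expect_warning(cw <- carcass_weight(0, 10), "zero")
  expect_equal(cw, 0)
  expect_error(carcass_weight(1000, 0), class = "vetamc_domain_error")

  expect_equal(live_weight(210, 0.7), 300)
  expect_equal(live_weight(35.25, 0.47), 75)
  expect_equal(live_weight(78, 0.78), 100)
  expect_error(live_weight(100, 0), class = "vetamc_domain_error")
  expect_error(live_weight(100, 1.2), class = "vetamc_domain_error")
  # live weight never below carcass weight for coefficients in (0,1]
  set.seed(1)
  cw <- runif(20, 1, 300)
  co <- runif(20, 0.1, 1)
  expect_true(all(live_weight(cw, co) >= cw))
})

make_inputs <- function() {
  census <- tibble::tibble(
    species = rep(c("cattle", "sheep", "goat", "pig", "chicken"), each = 2),
    year = rep(c(2009L, 2020L), 5),
    population = c(100000, 119691, 30000, 37435, 120000, 143853,
                   80000, 100000, 1.2e6, 1412901)
  )
  slaughter <- tibble::tibble(
    species = c("cattle", "pig", "chicken"),
    year = 2020L,
    count = c(1000, 30000, 1e6),
    total_weight_kg = c(210000, 30000 * 70.2, 1e6 * 1.4)
  )
  denominator_inputs(census, slaughter)
}

test_that("species biomass follows the per-species conventions", {
  inputs <- make_inputs()
  # cattle: census-year population x live weight (210 / 0.7 = 300)
  expect_equal(species_biomass("cattle", 2020, inputs), 119691 * 300)
  # goats: population x 37.5 kg standard weight
  expect_equal(species_biomass("goat", 2020, inputs), 143853 * 37.5)
  # chicken: number slaughtered x live weight (1.4 / 0.7 = 2)
  expect_equal(species_biomass("chicken", 2020, inputs), 1e6 * 2)
  # pig: slaughter-based (70.2 / 0.78 = 90)
  expect_equal(species_biomass("pig", 2020, inputs), 30000 * 90)
  # pig without slaughter data in a year errors, naming species and year
  expect_error(species_biomass("pig", 2019, inputs), "pig",
               class = "vetamc_domain_error")
})

test_that("national biomass is the sum over species and scales linearly", {
  inputs <- make_inputs()
  nb <- national_biomass(2020, inputs)
  per_species <- biomass_table(2020, inputs)
  expect_equal(nb$biomass_kg, sum(per_species$biomass_kg))

  # doubling every population and slaughter count doubles the total
  doubled <- denominator_inputs(
    dplyr::mutate(inputs$census, population = population * 2),
    dplyr::mutate(inputs$slaughter, count = count * 2,
                  total_weight_kg = total_weight_kg * 2))
  expect_equal(national_biomass(2020, doubled)$biomass_kg,
               2 * nb$biomass_kg, tolerance = 1e-12)
})

test_that("denominator inputs validate census structure", {
  census <- tibble::tibble(species = "cattle", year = 2020L,
                           population = 100)
  expect_error(denominator_inputs(census), "two census",
               class = "vetamc_schema_error")
  census3 <- tibble::tibble(species = "cattle", year = c(2009L, 2009L),
                            population = c(100, 120))
  expect_error(denominator_inputs(census3), class = "vetamc_schema_error")
})

test_that("denominators CSV round-trips through read_denominators", {
  inputs <- make_inputs()
  path <- withr::local_tempfile(fileext = ".csv")
  long <- dplyr::bind_rows(
    dplyr::transmute(inputs$census, species, field = "census_pop", year,
                     value = population),
    dplyr::transmute(inputs$slaughter, species, field = "slaughter_count",
                     year, value = count),
    dplyr::transmute(inputs$slaughter, species,
                     field = "slaughter_weight_kg", year,
                     value = total_weight_kg))
  readr::write_csv(long, path)
  back <- read_denominators(path)
  expect_equal(national_biomass(2020, back)$biomass_kg,
               national_biomass(2020, inputs)$biomass_kg)
})
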