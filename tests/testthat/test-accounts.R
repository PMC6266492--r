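test_that("bio item footprint converts tonnes over global yield", {
  # 1 t at 1000 kg/hm2 is exactly 1 hm2
  expect_identical(bio_item_footprint(1, 1000), 1)
  # split across cities: (600 + 400) t * 1000 / 1000 kg/hm2
  expect_identical(bio_item_footprint(c(600, 400), 1000), 1000)
  expect_identical(bio_item_footprint(c(0, 0, 0), 2744), 0)
  expect_error(bio_item_footprint(10, 0), "yield")
  expect_error(bio_item_footprint(-1, 1000), ">= 0")
})

test_that("energy item footprint divides per-capita consumption by the energy footprint", {
  r <- energy_item_footprint(c(30000, 20000), 50, 1000)
  expect_equal(r$consumption_per_capita, 50)
  expect_equal(r$area_per_capita, 1)
  z <- energy_item_footprint(0, 55, 1000)
  expect_equal(z$consumption_per_capita, 0)
  expect_equal(z$area_per_capita, 0)
  expect_error(energy_item_footprint(100, 55, 0), "population")
})

test_that("per-capita areas aggregate items within land types", {
  acc <- tiny_account(population = 1000)
  areas <- per_capita_area_by_land_type(acc)
  expect_named(areas, land_types(), ignore.order = TRUE)
  # grain: 1000 t / 1000 kg/hm2 = 1000 hm2 -> 1 hm2/person
  expect_equal(areas[["arable"]], 1)
  # fish: 250 t / 500 kg/hm2 = 500 hm2 -> 0.5
  expect_equal(areas[["water"]], 0.5)
  # coal: 50 GJ/person / 50 GJ/hm2; power: 10 / 1000
  expect_equal(areas[["fossil_energy"]], 1)
  expect_equal(areas[["built_up"]], 0.01)
  expect_equal(areas[["forest"]], 0)
})

test_that("items excluded from the land total are tallied but not aggregated", {
  bio <- tiny_bio()
  bio$in_land_total <- c(TRUE, FALSE)
  acc <- regional_account(bio, tiny_energy(), 1000, 2020)
  areas <- per_capita_area_by_land_type(acc)
  expect_equal(areas[["water"]], 0)
  # still present in the item-level table
  items <- account_item_footprints(acc)
  expect_equal(items$total_area_hm2[items$item == "fish"], 500)
})

test_that("physically built-up land adds to the energy-side built-up area", {
  acc <- regional_account(tiny_bio(), tiny_energy(), 1000, 2020,
                          built_up_area_hm2 = 90)
  expect_equal(per_capita_area_by_land_type(acc)[["built_up"]], 0.1)
})

test_that("aggregate_footprint applies equivalence factors and scales by N", {
  f <- default_factors()
  areas <- c(arable = 1, water = 0.5)
  fp <- aggregate_footprint(areas, f, 1000)
  expect_equal(fp$ef_per_capita, 1 * 2.51 + 0.5 * 0.37)
  expect_equal(fp$ef_total, 1000 * fp$ef_per_capita)
  z <- aggregate_footprint(c(arable = 0, forest = 0), f, 10)
  expect_equal(z$ef_per_capita, 0)
  expect_equal(z$ef_total, 0)
  bad <- structure(list(1), names = "swamp")
  expect_error(aggregate_footprint(c(swamp = 1), f, 10), "swamp")
})

test_that("footprint is additive over disjoint item sets", {
  f <- default_factors()
  bio <- tiny_bio(); energy <- tiny_energy()
  acc_bio <- regional_account(bio, tiny_energy()[0, ], 1000, 2020)
  acc_energy <- regional_account(bio[0, ], energy, 1000, 2020)
  acc_all <- regional_account(bio, energy, 1000, 2020)
  fp_b <- account_footprint(acc_bio, f)
  fp_e <- account_footprint(acc_energy, f)
  fp <- account_footprint(acc_all, f)
  expect_equal(fp$ef_per_capita, fp_b$ef_per_capita + fp_e$ef_per_capita)
  expect_equal(fp$by_land_type$equivalence_area_per_capita_hm2,
               fp_b$by_land_type$equivalence_area_per_capita_hm2 +
                 fp_e$by_land_type$equivalence_area_per_capita_hm2)
})

test_that("footprint is homogeneous of degree one in production", {
  f <- default_factors()
  scale_cities <- function(tbl, c) {
    for (cc in c("city_a", "city_b")) tbl[[cc]] <- tbl[[cc]] * c
    tbl
  }
  for (c in c(0.5, 3)) {
    a1 <- regional_account(tiny_bio(), tiny_energy(), 1000, 2020)
    a2 <- regional_account(scale_cities(tiny_bio(), c),
                           scale_cities(tiny_energy(), c), 1000, 2020)
    expect_equal(account_footprint(a2, f)$ef_per_capita,
                 c * account_footprint(a1, f)$ef_per_capita)
  }
})

test_that("empty accounts give all-zero areas", {
  acc <- regional_account(tiny_bio()[0, ], tiny_energy()[0, ], 1000, 2020)
  expect_true(all(per_capita_area_by_land_type(acc) == 0))
  expect_equal(nrow(account_item_footprints(acc)), 0)
})

test_that("account validation rejects bad schemas with named locations", {
  bio <- tiny_bio()
  bio$land_type[2] <- "ocean"
  expect_error(regional_account(bio, tiny_energy(), 1000, 2020),
               "row 2.*ocean")
  bio2 <- tiny_bio()
  bio2$city_a[1] <- -5
  expect_error(regional_account(bio2, tiny_energy(), 1000, 2020),
               "city_a")
  en <- tiny_energy()
  en$land_type[1] <- "arable"
  expect_error(regional_account(tiny_bio(), en, 1000, 2020),
               "fossil_energy or built_up")
  expect_error(regional_account(tiny_bio(), tiny_energy(), 0, 2020),
               "population")
})

test_that("factor tables validate completeness and ranges", {
  f <- default_factors()
  expect_setequal(f$land_type, land_types())
  expect_equal(f$equivalence_factor[f$land_type == "arable"], 2.51)
  expect_equal(f$yield_factor[f$land_type == "fossil_energy"], 0)
  expect_error(factor_table(c(arable = 2.51), c(arable = 1.66)),
               "missing land types")
  eq <- stats::setNames(rep(1, 6), land_types())
  expect_error(factor_table(eq, replace(eq, 1, -1)), ">= 0")
  expect_error(factor_table(eq, eq, biodiversity_fraction = 1.2), "0, 1")
})
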