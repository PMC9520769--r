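# Scenario registry, geometric validity, randomized generation and
# serialization.

test_that("registry ships the standard configurations", {
  ids <- scenario_names()
  expect_gte(length(ids), 20)
  # monolayer vessels x regimes
  for (v in c("well6", "T25", "T75", "T175"))
    expect_true(sprintf("mono_%s_HX_HG_deg", v) %in% ids)
  # named examples resolve with the documented geometry
  sc <- get_scenario("bead_24w_LG_NX_8M")
  expect_equal(sc$construct$radius_m * 1e3, 1.93, tolerance = 1e-2)
  expect_equal(sc$vessel$media_volume_ml, 2)
  expect_equal(sc$glucose_mM, 5.5)
  expect_equal(sc$construct$density, 8)
  sc <- get_scenario("cyl_3mm_20M_PX")
  expect_equal(sc$construct$radius_mm, 2.5)
  expect_equal(sc$construct$height_mm, 3)
  expect_equal(sc$construct$density, 20)
  expect_equal(sc$params$oxygen_regime, "PX")
  sc <- get_scenario("pellet_eppendorf_250k")
  expect_equal(sc$construct$cell_count, 250000)
  expect_equal(sc$vessel$media_volume_ml, 1)
  expect_equal(sc$glucose_mM, 25) # pellet literature is HG-only
  expect_error(get_scenario("not_a_scenario"), "unknown scenario")
})

test_that("every registry entry passes geometric validity", {
  for (id in scenario_names())
    expect_silent(validate_scenario(get_scenario(id)))
})

test_that("scenario invariants reject impossible configurations", {
  expect_error(
    culture_scenario("bad", vessel_spec("well96", media_volume_ml = 0.02),
                     construct_spec("bead", density = 4)),
    "smaller than the media volume")
  expect_error(
    culture_scenario("bad", vessel_spec("well6"),
                     construct_spec("cylinder", density = 4, height_mm = 3)),
    "not covered by media")
  expect_error(
    culture_scenario("bad", vessel_spec("well24"),
                     construct_spec("bead", density = 4),
                     schedule = list(exchange_days = c(2, 2),
                                     horizon_days = 3)),
    "strictly increasing")
  expect_error(
    culture_scenario("bad", vessel_spec("well24"),
                     construct_spec("bead", density = 4),
                     schedule = list(exchange_days = 5, horizon_days = 3)),
    "within the horizon")
})

test_that("registry round-trips through YAML serialization bit-identically", {
  for (id in c("bead_24w_LG_NX_8M", "mono_T175_HX_HG_deg",
               "cyl_1.5mm_20M_PX_HG", "pellet_eppendorf_250k_HX",
               "beads10_12w_HG_NX", "microagg_96well_35k_PX")) {
    sc <- get_scenario(id)
    expect_identical(scenario_from_yaml(scenario_to_yaml(sc)), sc)
  }
  # JSON export carries the resolved geometry
  js <- jsonlite::fromJSON(scenario_to_json(get_scenario("bead_24w_LG_NX_8M")))
  expect_equal(js$resolved$construct_radius_m, 1.93e-3, tolerance = 1e-2)
  expect_equal(js$resolved$dissolved_o2_uM, 0.2095 * 675 * 1.3,
               tolerance = 1e-9)
})

test_that("random scenarios are deterministic in the seed and always valid", {
  expect_identical(random_scenario(0), random_scenario(0))
  expect_false(identical(random_scenario(1), random_scenario(2)))
  for (s in 1:100)
    expect_silent(validate_scenario(random_scenario(s)))
  # zero-density bound produces a null-metabolism fixture
  sc0 <- random_scenario(5, bounds = list(density = c(0, 0),
                                          kinds = c("bead", "cylinder")))
  expect_equal(sc0$construct$density, 0)
  expect_error(random_scenario(1, bounds = list(density = c(-5, 100))),
               "bounds")
})

test_that("random generation does not disturb the global RNG stream", {
  set.seed(42)
  a <- stats::runif(1)
  set.seed(42)
  invisible(random_scenario(3))
  expect_identical(stats::runif(1), a)
})
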