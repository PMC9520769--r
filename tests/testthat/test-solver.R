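# Transient/steady solvers: null cases, analytical oracles, exchange
# semantics, conservation, internal cross-validation, determinism.

test_that("zero cell density leaves all fields at boundary values", {
  sc <- random_scenario(11, bounds = list(density = c(0, 0),
                                          kinds = "bead"))
  sc$schedule <- list(exchange_days = numeric(0), horizon_days = 1)
  res <- run_transient(sc, resolution = 10)
  bc <- dissolved_oxygen(sc$environment)
  expect_lt(max(abs(res$fields$o2 - bc)), 1e-6)
  expect_lt(max(abs(res$fields$glucose - sc$glucose_mM)), 1e-9)
  expect_lt(max(abs(res$fields$lactate)), 1e-9)
  st <- steady_state(sc, resolution = 10)
  expect_lt(max(abs(st$o2 - bc)), 1e-9)
})

test_that("uniform zero-order sphere sink reproduces qR^2/(6D)", {
  sc <- sphere_oracle_scenario(density = 2.4, vmax = 17)
  st <- steady_state(sc, resolution = 40)
  m <- st$mesh
  bc <- dissolved_oxygen(sc$environment)
  q <- zero_order_rate(17) * 2.4 / 3600 # uM/s
  R <- sc$construct$radius_m
  pred <- q * R^2 / (6 * sc$construct$diffusivities[["o2"]])
  got <- bc - min(st$o2[m$region == 2L])
  expect_lt(abs(got - pred) / pred, 0.01)
})

test_that("uniform zero-order slab with no-flux base reproduces qh^2/(2D)", {
  sc <- slab_q_oracle_scenario(density = 2.4, vmax = 17, height_mm = 1)
  st <- steady_state(sc, resolution = 40)
  m <- st$mesh
  bc <- dissolved_oxygen(sc$environment)
  q <- zero_order_rate(17) * 2.4 / 3600 # uM/s
  h <- 1e-3
  i <- which.min(st$o2)
  z1 <- m$coords$z[i] # bottom cell centre
  # two-layer series form: parabolic drop in the construct plus the linear
  # drop across the (fast) media column above it
  L_media <- m$geom$H - h
  pred <- q * (h^2 - z1^2) / (2 * sc$construct$diffusivities[["o2"]]) +
    q * h * L_media / sc$media_diffusivities[["o2"]]
  got <- bc - st$o2[i]
  expect_lt(abs(got - pred) / pred, 0.01)
})

test_that("constant areal sink under a media column reproduces jL/D", {
  sc <- slab_flux_oracle_scenario(n_areal = 30000, vmax = 17)
  st <- steady_state(sc, resolution = 40)
  m <- st$mesh
  bc <- dissolved_oxygen(sc$environment)
  j <- 30000 * 1e4 / 1e6 * zero_order_rate(17) * 1e-9 # mol/(m^2 h)
  pred <- j * m$geom$H / (sc$media_diffusivities[["o2"]] * 3600) * 1e3 # uM
  # linear profile: extrapolate the two bottom cells to the surface z = 0
  Csurf <- st$o2[1] - (st$o2[2] - st$o2[1]) /
    (m$coords$z[2] - m$coords$z[1]) * m$coords$z[1]
  expect_lt(abs((bc - Csurf) - pred) / pred, 0.01)
})

test_that("media exchange resets media only, and is idempotent", {
  sc <- get_scenario("bead_24w_LG_HX_8M")
  res <- run_transient(sc, resolution = 12,
                       times = c(0, 24, 48, 72 - 1 / 60, 72, 72 + 1 / 60, 84))
  st <- state_at(res, 72 - 1 / 60)
  m <- res$mesh
  expect_gt(max(st$lactate[m$region == 1L]), 0.5) # lactate accumulated
  ex <- apply_media_exchange(st, sc)
  expect_equal(max(abs(ex$lactate[m$region == 1L])), 0)
  expect_equal(min(ex$glucose[m$region == 1L]), sc$glucose_mM)
  expect_equal(min(ex$o2[m$region == 1L]), dissolved_oxygen(sc$environment))
  # construct interior untouched
  expect_identical(ex$lactate[m$region == 2L], st$lactate[m$region == 2L])
  expect_identical(ex$glucose[m$region == 2L], st$glucose[m$region == 2L])
  # idempotent
  expect_identical(apply_media_exchange(ex, sc), ex)
  # the integrated event matches the operator: one minute after the day-3
  # exchange the far-field media is fresh again (samples at the exact
  # event time carry the pre-event state, and media adjacent to the
  # depleted bead starts re-equilibrating immediately)
  st_after <- state_at(res, 72 + 1 / 60)
  far <- which.max(m$coords$z)
  expect_equal(st_after$glucose[far], sc$glucose_mM, tolerance = 1e-6)
  expect_equal(st_after$lactate[far], 0, tolerance = 1e-3)
})

test_that("glucose and lactate inventories close against integrated rates", {
  sc <- get_scenario("bead_24w_LG_HX_8M")
  sc$schedule <- list(exchange_days = numeric(0), horizon_days = 3)
  res <- run_transient(sc, resolution = 16)
  k <- length(res$times)
  consumed <- res$aux$glucose_consumed[k]
  produced <- res$aux$lactate_produced[k]
  expect_gt(consumed, 0)
  inv_g0 <- solute_inventory(res, 0, "glucose")
  inv_g1 <- solute_inventory(res, max(res$times), "glucose")
  expect_lt(abs(inv_g1 + consumed - inv_g0) / inv_g0, 1e-3)
  inv_l1 <- solute_inventory(res, max(res$times), "lactate")
  expect_lt(abs(inv_l1 - produced) / produced, 1e-3)
})

test_that("steady oxygen balances boundary influx against consumption", {
  sc <- get_scenario("bead_24w_LG_NX_8M")
  st <- steady_state(sc, resolution = 30)
  p <- npmicroenv:::.solver_parms(st$mesh, sc, "oxygen_only")
  influx <- sum(p$dir$g * (p$dir$value - st$o2[p$dir$cells]))
  lin <- npmicroenv:::ocr_linearization(sc$buffer$ph_fresh, sc$params)
  cons <- sum(lin$vmax_eff * p$rho * st$o2 / (lin$km_eff[1] + st$o2) *
                p$vol * p$count)
  expect_lt(abs(influx - cons) / cons, 0.005)
})

test_that("steady state agrees with the long-time oxygen-only transient", {
  for (id in c("bead_24w_LG_NX_8M", "bead_24w_LG_PX_4M")) {
    sc <- get_scenario(id)
    m <- build_mesh(sc, 20)
    st <- steady_state(sc, mesh = m)
    res <- run_transient(sc, mesh = m, mode = "oxygen_only",
                         times = c(0, 24, 48, 72))
    env <- sc$environment
    d <- percent_o2_equivalent(res$fields$o2[, 4], env) -
      percent_o2_equivalent(st$o2, env)
    expect_lt(max(abs(d)), 0.1) # within 0.1 %O2 everywhere
  }
})

test_that("identical scenario and resolution give bit-identical reruns", {
  sc <- get_scenario("bead_24w_LG_NX_4M")
  r1 <- run_transient(sc, resolution = 12)
  r2 <- run_transient(sc, resolution = 12)
  expect_identical(r1$fields, r2$fields)
  expect_identical(r1$aux, r2$aux)
})

test_that("minimum oxygen responds monotonically to density and Vmax", {
  sc <- get_scenario("bead_24w_LG_NX_4M")
  m <- build_mesh(sc, 14)
  base <- min(steady_state(sc, mesh = m)$o2)
  sc_d <- sc; sc_d$construct$density <- 8
  expect_lt(min(steady_state(sc_d, resolution = 14)$o2), base)
  sc_v <- sc; sc_v$params <- metabolic_params("NX", "LG", "degenerated")
  expect_lt(min(steady_state(sc_v, mesh = m)$o2), base)
})
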