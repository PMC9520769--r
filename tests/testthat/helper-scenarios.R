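# Shared fixture builders.  Everything is generated in code; oracle
# scenarios use degenerate parameter choices (tiny Km -> zero-order
# kinetics, zero buffer slope -> fixed pH, near-infinite media diffusivity
# -> uniform media) so closed-form solutions apply.

FAST_MEDIA <- c(o2 = 1e-6, glucose = 1e-6, lactate = 1e-6) # ~uniform media

zero_order_params <- function(vmax = 17) {
  metabolic_params("NX", "LG", "animal", ocr_vmax = vmax, ocr_km = 1e-9)
}

# zero-order rate actually realized at pH 7.4 under the scaled law (uM/h
# per 10^6 cells/ml)
zero_order_rate <- function(vmax = 17, ph = 7.4) vmax * (ph - 4.95)

# Uniformly consuming sphere whose surface effectively sees the boundary
# concentration: bead in a 24-well under near-infinite media diffusivity.
sphere_oracle_scenario <- function(density = 2.4, vmax = 17) {
  culture_scenario(
    id = "oracle_sphere",
    vessel = vessel_spec("well24"),
    construct = construct_spec("bead", density = density),
    environment = gas_environment("NX"),
    buffer = buffer_model(slope = 0),
    media_diffusivities = FAST_MEDIA,
    params = zero_order_params(vmax),
    schedule = list(exchange_days = numeric(0), horizon_days = 3))
}

# Uniformly consuming full-width slab with a no-flux base: cylinder
# construct spanning the whole well base, fast media above.
slab_q_oracle_scenario <- function(density = 2.4, vmax = 17, height_mm = 1) {
  vs <- vessel_spec("well24")
  culture_scenario(
    id = "oracle_slab_q",
    vessel = vs,
    construct = construct_spec(
      "cylinder", density = density,
      radius_mm = 1e3 * npmicroenv:::vessel_radius(vs),
      height_mm = height_mm),
    environment = gas_environment("NX"),
    buffer = buffer_model(slope = 0),
    media_diffusivities = FAST_MEDIA,
    params = zero_order_params(vmax),
    schedule = list(exchange_days = numeric(0), horizon_days = 3))
}

# Constant areal sink under a media column: monolayer with zero growth and
# zero-order kinetics.
slab_flux_oracle_scenario <- function(n_areal = 30000, vmax = 17) {
  culture_scenario(
    id = "oracle_slab_flux",
    vessel = vessel_spec("well6"),
    construct = construct_spec(
      "monolayer",
      seeding = cell_population(initial_count = n_areal, growth_rate = 0,
                                confluency_cap = n_areal)),
    environment = gas_environment("NX"),
    buffer = buffer_model(slope = 0),
    params = zero_order_params(vmax),
    schedule = list(exchange_days = numeric(0), horizon_days = 3))
}

# Construct-region oxygen minimum in %O2 at the day-3 pre-exchange snapshot.
day3_min_o2_pct <- function(result)
  microenv_stat(result, 72 - 1 / 60, "o2", "min", "construct", "percent")

day3_min_ph <- function(result)
  microenv_stat(result, 72 - 1 / 60, "ph", "min", "construct")
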