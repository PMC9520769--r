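# Registry of named culture scenarios: the standard configurations used
# across the disc cell-culture field (monolayer expansion vessels, single
# and multiple alginate beads, cylindrical hydrogel constructs, pellets and
# microaggregates).

.GLC_LEVEL <- c(LG = 5.5, HG = 25)

.registry_table <- local({
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- list(...)
  # 2D monolayer expansion: vessel x oxygen x glucose x phenotype
  for (v in c("well6", "T25", "T75", "T175"))
    for (o2 in c("NX", "PX", "HX"))
      for (gl in c("LG", "HG"))
        for (ph in c("animal", "degenerated"))
          add(id = sprintf("mono_%s_%s_%s_%s", v, o2, gl,
                           if (ph == "animal") "animal" else "deg"),
              kind = "monolayer", vessel = v, o2 = o2, gl = gl, phen = ph)
  # Single 30 ul alginate bead in a 24-well with 2 ml
  for (d in c(2, 4, 8))
    for (gl in c("LG", "HG"))
      for (o2 in c("NX", "PX", "HX"))
        for (ph in c("animal", "degenerated"))
          add(id = sprintf("bead_24w_%s_%s_%dM%s", gl, o2, d,
                           if (ph == "animal") "" else "_deg"),
              kind = "bead", vessel = "well24", o2 = o2, gl = gl,
              phen = ph, density = d)
  # Multiple beads (4 or 10, 4e6 cells/ml) in a 12-well
  for (n in c(4, 10))
    for (gl in c("LG", "HG"))
      for (o2 in c("NX", "PX", "HX"))
        add(id = sprintf("beads%d_12w_%s_%s", n, gl, o2),
            kind = "multibead", vessel = "well12", o2 = o2, gl = gl,
            phen = "animal", density = 4, n = n)
  # Cylindrical hydrogel constructs (animal rates only)
  for (h in c(1.5, 3))
    for (d in c(4, 20))
      for (gl in c("LG", "HG"))
        for (o2 in c("NX", "PX", "HX"))
          add(id = sprintf("cyl_%smm_%dM_%s%s", format(h), d, o2,
                           if (gl == "LG") "" else "_HG"),
              kind = "cylinder", vessel = "well24", o2 = o2, gl = gl,
              phen = "animal", density = d, height = h)
  # Pellets and microaggregates (HG media throughout)
  for (o2 in c("NX", "PX", "HX")) {
    sfx <- if (o2 == "NX") "" else paste0("_", o2)
    add(id = paste0("pellet_eppendorf_250k", sfx), kind = "pellet",
        vessel = "eppendorf", o2 = o2, gl = "HG", phen = "animal",
        cells = 250000)
    add(id = paste0("pellet_96well_250k", sfx), kind = "pellet",
        vessel = "well96", o2 = o2, gl = "HG", phen = "animal",
        cells = 250000, volume_ml = 0.2)
    add(id = paste0("microagg_96well_35k", sfx), kind = "pellet",
        vessel = "well96", o2 = o2, gl = "HG", phen = "animal",
        cells = 35000, volume_ml = 0.05)
  }
  rows
})

.registry_ids <- vapply(.registry_table, `[[`, "", "id")

.build_registry_scenario <- function(row) {
  env <- gas_environment(row$o2)
  par <- metabolic_params(row$o2, row$gl, row$phen)
  glc <- unname(.GLC_LEVEL[row$gl])
  switch(row$kind,
    monolayer = culture_scenario(
      id = row$id, vessel = vessel_spec(row$vessel),
      construct = construct_spec("monolayer", seeding = cell_population()),
      environment = env, glucose_mM = glc, params = par,
      schedule = list(exchange_days = 3.5, horizon_days = 7)),
    bead = culture_scenario(
      id = row$id, vessel = vessel_spec(row$vessel),
      construct = construct_spec("bead", density = row$density),
      environment = env, glucose_mM = glc, params = par,
      schedule = list(exchange_days = 3, horizon_days = 3.5)),
    multibead = culture_scenario(
      id = row$id, vessel = vessel_spec(row$vessel),
      construct = construct_spec("bead", density = row$density),
      n_constructs = row$n, environment = env, glucose_mM = glc,
      params = par, schedule = list(exchange_days = 3, horizon_days = 3.5)),
    cylinder = culture_scenario(
      id = row$id, vessel = vessel_spec(row$vessel),
      construct = construct_spec("cylinder", density = row$density,
                                 radius_mm = 2.5, height_mm = row$height),
      environment = env, glucose_mM = glc, params = par,
      schedule = list(exchange_days = 3.5, horizon_days = 7)),
    pellet = culture_scenario(
      id = row$id,
      vessel = vessel_spec(row$vessel, media_volume_ml = row$volume_ml),
      construct = construct_spec("pellet", cell_count = row$cells),
      environment = env, glucose_mM = glc, params = par,
      schedule = list(exchange_days = 3, horizon_days = 3.5)))
}

#' Retrieve a named scenario from the registry
#'
#' The registry covers the standard configurations of the field: monolayer
#' expansion in 6-well plates and T-25/75/175 flasks, single 30 ul alginate
#' beads at 2/4/8 x 10^6 cells/ml in a 24-well, 4- and 10-bead cultures in
#' a 12-well, cylindrical constructs (r 2.5 mm, h 1.5 or 3 mm) at 4 or
#' 20 x 10^6 cells/ml, and 250k-cell pellets / 35k-cell microaggregates,
#' each crossed with the NX/PX/HX incubator settings and LG/HG media where
#' applicable.
#'
#' @param id Scenario identifier, e.g. `"bead_24w_LG_NX_8M"`,
#'   `"cyl_3mm_20M_PX"`, `"pellet_eppendorf_250k"`.
#' @return A [culture_scenario()].
#' @seealso [scenario_names()], [list_scenarios()], [random_scenario()]
#' @export
get_scenario <- function(id) {
  i <- match(id, .registry_ids)
  if (is.na(i))
    stop("unknown scenario '", id, "'; valid ids include:\n  ",
         paste(utils::head(.registry_ids, 25), collapse = ", "),
         ", ... (see scenario_names())")
  .build_registry_scenario(.registry_table[[i]])
}

#' All registry scenario identifiers
#' @return Character vector of valid ids for [get_scenario()].
#' @export
scenario_names <- function() .registry_ids

#' Tabulate the scenario registry
#'
#' @return A data.frame with one row per registry entry: id, construct
#'   kind, vessel, oxygen regime, glucose regime, phenotype.
#' @export
list_scenarios <- function() {
  data.frame(
    id = .registry_ids,
    kind = vapply(.registry_table, `[[`, "", "kind"),
    vessel = vapply(.registry_table, `[[`, "", "vessel"),
    oxygen = vapply(.registry_table, `[[`, "", "o2"),
    glucose = vapply(.registry_table, `[[`, "", "gl"),
    phenotype = vapply(.registry_table, `[[`, "", "phen"),
    stringsAsFactors = FALSE)
}

#' Randomized scenario generator for property testing
#'
#' Draws a physically valid random scenario (kind, vessel, density, gas and
#' glucose regimes, schedule) deterministically from an integer seed.  The
#' construct is always sized to fit its vessel, so every generated scenario
#' passes [validate_scenario()].
#'
#' @param seed Integer seed; equal seeds give identical scenarios.
#' @param bounds List of parameter ranges: `density` (10^6 cells/ml),
#'   `kinds` (subset of bead/cylinder/pellet/monolayer).
#' @return A [culture_scenario()].
#' @export
random_scenario <- function(seed,
                            bounds = list(density = c(0, 50),
                                          kinds = c("bead", "cylinder",
                                                    "pellet", "monolayer"))) {
  if (is.null(bounds$density)) bounds$density <- c(0, 50)
  if (is.null(bounds$kinds))
    bounds$kinds <- c("bead", "cylinder", "pellet", "monolayer")
  if (any(bounds$density < 0) || any(bounds$density > 50) ||
      bounds$density[1] > bounds$density[2])
    stop("density bounds must lie in [0, 50] x 10^6 cells/ml")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  kind <- sample(bounds$kinds, 1)
  o2 <- sample(c("NX", "PX", "HX"), 1)
  gl <- sample(c("LG", "HG"), 1)
  phen <- sample(c("animal", "degenerated"), 1)
  dens <- stats::runif(1, bounds$density[1], bounds$density[2])
  env <- gas_environment(o2)
  par <- metabolic_params(o2, gl, phen)
  glc <- unname(.GLC_LEVEL[gl])
  horizon <- round(stats::runif(1, 2, 7), 2)
  sched <- list(exchange_days = round(horizon * stats::runif(1, 0.4, 0.9), 2),
                horizon_days = horizon)
  if (kind == "monolayer") {
    vs <- vessel_spec(sample(c("well6", "T25", "T75", "T175"), 1))
    cs <- construct_spec("monolayer",
                         seeding = cell_population(
                           initial_count = round(stats::runif(1, 1000, 10000)),
                           growth_rate = round(stats::runif(1, 0.1, 0.5), 3)))
  } else if (kind == "bead") {
    vs <- vessel_spec(sample(c("well12", "well24"), 1))
    cs <- construct_spec("bead", density = dens,
                         volume_ul = round(stats::runif(1, 10, 50), 1))
  } else if (kind == "cylinder") {
    vs <- vessel_spec(sample(c("well12", "well24"), 1))
    rmax <- min(2.5, 1e3 * vessel_radius(vs) * 0.9)
    cs <- construct_spec("cylinder",
                         density = dens,
                         radius_mm = round(stats::runif(1, 1, rmax), 2),
                         height_mm = round(stats::runif(1, 1, 3), 2))
  } else {
    vs <- vessel_spec(sample(c("eppendorf", "well96"), 1))
    cs <- construct_spec("pellet",
                         cell_count = round(stats::runif(1, 2e4, 5e5)),
                         packing_density = round(stats::runif(1, 100, 300)))
  }
  culture_scenario(id = sprintf("random_%d_%s", seed, kind),
                   vessel = vs, construct = cs, environment = env,
                   glucose_mM = glc, params = par, schedule = sched,
                   seed = as.integer(seed))
}
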