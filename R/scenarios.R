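# Culture-configuration data structures: vessels, constructs, and the
# CultureScenario container that fully defines one simulation.

# Catalogue base areas (cm^2) for standard Corning/SARSTEDT-style vessels;
# the eppendorf is a truncated cone described by its bottom radius and
# half-angle (standard 1.5 ml tube dimensions).
.VESSEL_CATALOGUE <- list(
  well6  = list(shape = "cylinder", base_area_cm2 = 9.6,  default_volume_ml = 2),
  well12 = list(shape = "cylinder", base_area_cm2 = 3.8,  default_volume_ml = 2),
  well24 = list(shape = "cylinder", base_area_cm2 = 1.9,  default_volume_ml = 2),
  well96 = list(shape = "cylinder", base_area_cm2 = 0.32, default_volume_ml = 0.2),
  T25    = list(shape = "cylinder", base_area_cm2 = 25,   default_volume_ml = 5),
  T75    = list(shape = "cylinder", base_area_cm2 = 75,   default_volume_ml = 10),
  T175   = list(shape = "cylinder", base_area_cm2 = 175,  default_volume_ml = 20),
  eppendorf = list(shape = "truncated_cone", r_bottom_mm = 1.5,
                   half_angle_deg = 8.5, default_volume_ml = 1)
)

# Material diffusivities (m^2/s) for oxygen, glucose, lactate.
.DIFF_MEDIA    <- c(o2 = 2.8e-9,  glucose = 5.67e-10, lactate = 5.68e-10)
.DIFF_ALGINATE <- c(o2 = 1.8e-9,  glucose = 5.1e-10,  lactate = 4.67e-10)
.DIFF_HYDROGEL <- c(o2 = 2.1e-9,  glucose = 6.3e-10,  lactate = 5.1e-10)

#' Culture vessel specification
#'
#' Standard plates and flasks are modeled as vertical cylinders of the
#' catalogue base area; the Eppendorf tube as a truncated cone.  Media fill
#' height follows from the working volume and the vessel geometry.
#'
#' @param kind One of `"well6"`, `"well12"`, `"well24"`, `"well96"`,
#'   `"T25"`, `"T75"`, `"T175"`, `"eppendorf"`.
#' @param media_volume_ml Working media volume in ml; defaults to the
#'   standard working volume for the vessel.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(kind, media_volume_ml = NULL) {
  kind <- match.arg(kind, names(.VESSEL_CATALOGUE))
  cat_ <- .VESSEL_CATALOGUE[[kind]]
  if (is.null(media_volume_ml)) media_volume_ml <- cat_$default_volume_ml
  if (media_volume_ml <= 0) stop("media volume must be positive")
  structure(list(kind = kind, media_volume_ml = as.numeric(media_volume_ml)),
            class = "vessel_spec")
}

vessel_shape <- function(vessel) .VESSEL_CATALOGUE[[vessel$kind]]$shape

# Radius (m) of a cylindrical vessel.
vessel_radius <- function(vessel) {
  cat_ <- .VESSEL_CATALOGUE[[vessel$kind]]
  if (cat_$shape != "cylinder") stop("vessel is not cylindrical")
  sqrt(cat_$base_area_cm2 * 1e-4 / pi)
}

# Cone wall radius (m) at height z (m) above the eppendorf base.
cone_radius_at <- function(vessel, z) {
  cat_ <- .VESSEL_CATALOGUE[[vessel$kind]]
  cat_$r_bottom_mm * 1e-3 + z * tan(cat_$half_angle_deg * pi / 180)
}

# Liquid volume (m^3) of an eppendorf filled to height h (m).
cone_volume_to <- function(vessel, h) {
  cat_ <- .VESSEL_CATALOGUE[[vessel$kind]]
  r0 <- cat_$r_bottom_mm * 1e-3
  r1 <- cone_radius_at(vessel, h)
  pi * h * (r0^2 + r0 * r1 + r1^2) / 3
}

# Fill height (m) for a total liquid volume (m^3).
vessel_fill_height <- function(vessel, volume_m3) {
  if (volume_m3 <= 0) stop("fill volume must be positive")
  if (vessel_shape(vessel) == "cylinder") {
    area <- .VESSEL_CATALOGUE[[vessel$kind]]$base_area_cm2 * 1e-4
    volume_m3 / area
  } else {
    stats::uniroot(function(h) cone_volume_to(vessel, h) - volume_m3,
                   c(1e-6, 1), tol = 1e-14)$root
  }
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat(sprintf("<vessel_spec> %s, %g ml media\n", x$kind, x$media_volume_ml))
  invisible(x)
}

#' Cultured construct specification
#'
#' Describes the cell-laden phase of a scenario: an adherent monolayer, a
#' 30 ul alginate bead, a cylindrical hydrogel construct, or a
#' pellet/microaggregate (a sphere of cells at a packing density).
#'
#' @param kind `"monolayer"`, `"bead"`, `"cylinder"` or `"pellet"`.
#' @param density Cell seeding density in 10^6 cells/ml (3D kinds).
#' @param volume_ul Bead volume in ul (30 ul gives radius ~1.93 mm).
#' @param radius_mm,height_mm Cylinder dimensions in mm.
#' @param cell_count Total cells in a pellet/microaggregate.
#' @param packing_density Pellet internal packing in 10^6 cells/ml; the
#'   pellet radius follows from `cell_count / packing_density`.
#' @param diffusivities Named vector (`o2`, `glucose`, `lactate`) of
#'   within-construct diffusion coefficients in m^2/s.  Defaults:
#'   alginate-specific values for beads, hydrogel averages for cylinders
#'   and pellets.
#' @param seeding A [cell_population()] (monolayer kind only).
#' @return An object of class `construct_spec` carrying the derived
#'   geometry (`radius_m`, `height_m`, `volume_m3`).
#' @export
construct_spec <- function(kind = c("monolayer", "bead", "cylinder", "pellet"),
                           density = 0,
                           volume_ul = 30,
                           radius_mm = 2.5,
                           height_mm = 3,
                           cell_count = 250000,
                           packing_density = 200,
                           diffusivities = NULL,
                           seeding = NULL) {
  kind <- match.arg(kind)
  if (density < 0) stop("cell density must be non-negative")
  if (is.null(diffusivities))
    diffusivities <- switch(kind, bead = .DIFF_ALGINATE,
                            monolayer = .DIFF_MEDIA, .DIFF_HYDROGEL)
  if (!all(c("o2", "glucose", "lactate") %in% names(diffusivities)))
    stop("diffusivities must be named o2, glucose, lactate")
  if (any(diffusivities <= 0)) stop("diffusivities must be positive")
  sp <- list(kind = kind, density = as.numeric(density),
             diffusivities = diffusivities[c("o2", "glucose", "lactate")])
  if (kind == "monolayer") {
    if (is.null(seeding)) seeding <- cell_population()
    sp$seeding <- seeding
    sp$volume_m3 <- 0
  } else if (kind == "bead") {
    if (volume_ul <= 0) stop("bead volume must be positive")
    sp$volume_ul <- as.numeric(volume_ul)
    sp$volume_m3 <- volume_ul * 1e-9
    sp$radius_m <- (3 * sp$volume_m3 / (4 * pi))^(1 / 3)
  } else if (kind == "cylinder") {
    if (radius_mm <= 0 || height_mm <= 0) stop("cylinder dimensions must be positive")
    sp$radius_mm <- as.numeric(radius_mm)
    sp$height_mm <- as.numeric(height_mm)
    sp$radius_m <- radius_mm * 1e-3
    sp$height_m <- height_mm * 1e-3
    sp$volume_m3 <- pi * sp$radius_m^2 * sp$height_m
  } else { # pellet
    if (cell_count <= 0 || packing_density <= 0)
      stop("pellet cell count and packing density must be positive")
    sp$cell_count <- as.numeric(cell_count)
    sp$packing_density <- as.numeric(packing_density)
    sp$density <- as.numeric(packing_density)
    sp$volume_m3 <- cell_count / (packing_density * 1e6) * 1e-6 # ml -> m^3
    sp$radius_m <- (3 * sp$volume_m3 / (4 * pi))^(1 / 3)
  }
  structure(sp, class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  dim_txt <- switch(x$kind,
    monolayer = "adherent layer",
    bead = sprintf("%g ul, radius %.3f mm", x$volume_ul, 1e3 * x$radius_m),
    cylinder = sprintf("r %.2f mm x h %.2f mm", x$radius_mm, x$height_mm),
    pellet = sprintf("%g cells, radius %.3f mm", x$cell_count, 1e3 * x$radius_m))
  cat(sprintf("<construct_spec> %s (%s), %g x10^6 cells/ml\n",
              x$kind, dim_txt, x$density))
  invisible(x)
}

#' Complete culture scenario
#'
#' Assembles vessel, construct(s), gas environment, media composition,
#' metabolic parameters and feeding schedule into the single object the
#' solvers consume.
#'
#' @param id Character scenario identifier.
#' @param vessel A [vessel_spec()].
#' @param construct A [construct_spec()].
#' @param n_constructs Number of identical constructs in the vessel
#'   (multi-bead cultures); monolayer scenarios must use 1.
#' @param environment A [gas_environment()].
#' @param glucose_mM Fresh-media glucose (5.5 for LG, 25 for HG).
#' @param buffer A [buffer_model()].
#' @param media_diffusivities Named solute diffusivities of culture media in
#'   m^2/s.
#' @param params A [metabolic_params()].
#' @param schedule List with `exchange_days` (strictly increasing media
#'   exchange times, days) and `horizon_days` (simulation length, days).
#' @param seed Optional integer recorded for randomized generation.
#' @return An object of class `culture_scenario`.
#' @export
culture_scenario <- function(id,
                             vessel,
                             construct,
                             n_constructs = 1,
                             environment = gas_environment("NX"),
                             glucose_mM = 5.5,
                             buffer = buffer_model(),
                             media_diffusivities = .DIFF_MEDIA,
                             params = metabolic_params(),
                             schedule = list(exchange_days = 3,
                                             horizon_days = 3.5),
                             seed = NULL) {
  sc <- structure(
    list(id = as.character(id), vessel = vessel, construct = construct,
         n_constructs = as.integer(n_constructs), environment = environment,
         glucose_mM = as.numeric(glucose_mM), buffer = buffer,
         media_diffusivities =
           media_diffusivities[c("o2", "glucose", "lactate")],
         params = params, schedule = schedule, seed = seed),
    class = "culture_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a culture scenario
#'
#' Checks the geometric and schedule invariants: positive media volume with
#' constructs strictly smaller than the media volume, constructs fitting
#' inside (and covered by) the media column, construct diffusivities not
#' exceeding the media diffusivities, and a strictly increasing exchange
#' schedule inside the horizon.
#'
#' @param sc A [culture_scenario()].
#' @return The scenario, invisibly; errors on violation.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "culture_scenario"))
  cs <- sc$construct
  if (sc$n_constructs < 1) stop("n_constructs must be >= 1")
  if (cs$kind == "monolayer" && sc$n_constructs != 1)
    stop("monolayer scenarios use a single construct")
  # hydrogel diffusivities are normally below the media values, but the
  # compiled hydrogel-average glucose coefficient slightly exceeds the
  # media one, so this is not enforced as an error
  v_constructs <- sc$n_constructs * cs$volume_m3
  v_media <- sc$vessel$media_volume_ml * 1e-6
  if (v_constructs >= v_media)
    stop("total construct volume must be smaller than the media volume")
  h_fill <- vessel_fill_height(sc$vessel, v_media + v_constructs)
  if (cs$kind %in% c("bead", "pellet")) {
    if (2 * cs$radius_m > h_fill)
      stop("construct is not covered by media: fill height too small")
    if (vessel_shape(sc$vessel) == "cylinder") {
      if (cs$radius_m > vessel_radius(sc$vessel))
        stop("construct does not fit inside the vessel")
    } else {
      if (cs$radius_m > cone_radius_at(sc$vessel, cs$radius_m))
        stop("construct does not fit inside the vessel cone")
    }
  } else if (cs$kind == "cylinder") {
    if (vessel_shape(sc$vessel) != "cylinder")
      stop("cylindrical constructs require a cylindrical vessel")
    if (cs$radius_m > vessel_radius(sc$vessel))
      stop("construct does not fit inside the vessel")
    if (cs$height_m >= h_fill)
      stop("construct is not covered by media: fill height too small")
  }
  ex <- sc$schedule$exchange_days
  if (length(ex)) {
    if (any(ex <= 0) || is.unsorted(ex, strictly = TRUE))
      stop("exchange times must be positive and strictly increasing")
    if (any(ex > sc$schedule$horizon_days))
      stop("exchange times must lie within the horizon")
  }
  if (sc$schedule$horizon_days <= 0) stop("horizon must be positive")
  invisible(sc)
}

#' @export
print.culture_scenario <- function(x, ...) {
  cat(sprintf("<culture_scenario> %s\n", x$id))
  cat(sprintf("  %d x %s in %s (%g ml), %s incubator, %g mM glucose\n",
              x$n_constructs, x$construct$kind, x$vessel$kind,
              x$vessel$media_volume_ml, x$environment$label, x$glucose_mM))
  cat(sprintf("  rates %s+%s/%s; exchanges at day %s over %g d\n",
              x$params$oxygen_regime, x$params$glucose_regime,
              x$params$phenotype,
              paste(x$schedule$exchange_days, collapse = ", "),
              x$schedule$horizon_days))
  invisible(x)
}
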