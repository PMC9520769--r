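# Scenario serialization: structured-text (YAML) configuration documents
# and JSON export of resolved scenarios.  Only defining inputs are stored;
# derived geometry is recomputed on load, so a round trip reproduces the
# scenario exactly.

scenario_config <- function(sc) {
  stopifnot(inherits(sc, "culture_scenario"))
  cs <- sc$construct
  construct <- list(kind = cs$kind)
  if (cs$kind == "monolayer") {
    construct$seeding <- unclass(cs$seeding)
  } else if (cs$kind == "bead") {
    construct$density <- cs$density
    construct$volume_ul <- cs$volume_ul
  } else if (cs$kind == "cylinder") {
    construct$density <- cs$density
    construct$radius_mm <- cs$radius_mm
    construct$height_mm <- cs$height_mm
  } else {
    construct$cell_count <- cs$cell_count
    construct$packing_density <- cs$packing_density
  }
  construct$diffusivities <- as.list(cs$diffusivities)
  p <- sc$params
  list(
    id = sc$id,
    vessel = unclass(sc$vessel),
    construct = construct,
    n_constructs = sc$n_constructs,
    environment = unclass(sc$environment),
    glucose_mM = sc$glucose_mM,
    buffer = unclass(sc$buffer),
    media_diffusivities = as.list(sc$media_diffusivities),
    params = list(
      oxygen_regime = p$oxygen_regime, glucose_regime = p$glucose_regime,
      phenotype = p$phenotype, ocr_vmax = p$ocr_vmax, ocr_km = p$ocr_km,
      ocr_ph_offset = p$ocr_ph_offset, ocr_ph_ref = p$ocr_ph_ref,
      gcr_vmax = p$gcr_vmax, gcr_km = p$gcr_km,
      lac_gluc_ratio = p$lac_gluc_ratio, lpr_vmax = p$lpr_vmax,
      lpr_mode = p$lpr_mode,
      lpr_ph_anchors = list(ph = as.numeric(p$lpr_ph_anchors[, 1]),
                            mult = as.numeric(p$lpr_ph_anchors[, 2])),
      ocr_ph_form = p$ocr_ph_form),
    schedule = sc$schedule,
    seed = sc$seed)
}

scenario_from_config <- function(conf) {
  cc <- conf$construct
  construct_args <- list(kind = cc$kind,
                         diffusivities = unlist(cc$diffusivities))
  if (cc$kind == "monolayer") {
    construct_args$seeding <- do.call(cell_population, cc$seeding)
  } else if (cc$kind == "bead") {
    construct_args$density <- cc$density
    construct_args$volume_ul <- cc$volume_ul
  } else if (cc$kind == "cylinder") {
    construct_args$density <- cc$density
    construct_args$radius_mm <- cc$radius_mm
    construct_args$height_mm <- cc$height_mm
  } else {
    construct_args$cell_count <- cc$cell_count
    construct_args$packing_density <- cc$packing_density
  }
  pp <- conf$params
  pp$lpr_ph_anchors <- cbind(ph = unlist(pp$lpr_ph_anchors$ph),
                             mult = unlist(pp$lpr_ph_anchors$mult))
  culture_scenario(
    id = conf$id,
    vessel = do.call(vessel_spec, conf$vessel),
    construct = do.call(construct_spec, construct_args),
    n_constructs = conf$n_constructs,
    environment = do.call(gas_environment, conf$environment),
    glucose_mM = conf$glucose_mM,
    buffer = do.call(buffer_model, conf$buffer),
    media_diffusivities = unlist(conf$media_diffusivities),
    params = do.call(metabolic_params, pp),
    schedule = list(exchange_days = unlist(conf$schedule$exchange_days),
                    horizon_days = conf$schedule$horizon_days),
    seed = conf$seed)
}

#' Write a scenario as a structured-text (YAML) configuration document
#'
#' Only defining inputs are serialized; derived quantities (bead radius,
#' fill height, ...) are recomputed on load so that
#' `scenario_from_yaml(scenario_to_yaml(sc))` reproduces `sc` exactly.
#'
#' @param sc A [culture_scenario()].
#' @param path Output file; if `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
scenario_to_yaml <- function(sc, path = NULL) {
  txt <- yaml::as.yaml(scenario_config(sc), precision = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a scenario from a YAML configuration document
#'
#' @param path File path, or a YAML string produced by [scenario_to_yaml()].
#' @return A [culture_scenario()].
#' @export
scenario_from_yaml <- function(path) {
  is_file <- length(path) == 1L && !grepl("\n", path, fixed = TRUE) &&
    file.exists(path)
  conf <- if (is_file) yaml::read_yaml(path) else yaml::yaml.load(path)
  scenario_from_config(conf)
}

#' Export a resolved scenario as JSON
#'
#' Includes derived geometry (construct radius/height/volume, media fill
#' height) alongside the defining configuration.
#'
#' @inheritParams scenario_to_yaml
#' @return `path` invisibly, or the JSON string.
#' @export
scenario_to_json <- function(sc, path = NULL) {
  conf <- scenario_config(sc)
  v_total <- sc$vessel$media_volume_ml * 1e-6 +
    sc$n_constructs * sc$construct$volume_m3
  conf$resolved <- list(
    construct_volume_m3 = sc$construct$volume_m3,
    construct_radius_m = sc$construct$radius_m,
    construct_height_m = sc$construct$height_m,
    fill_height_m = vessel_fill_height(sc$vessel, v_total),
    dissolved_o2_uM = dissolved_oxygen(sc$environment),
    boundary_percent_o2 = effective_gas_percent(sc$environment))
  txt <- jsonlite::toJSON(conf, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
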