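# Incubator gas settings and Henry's-law dissolved-oxygen conversion.

.GAS_PRESETS <- list(
  NX = 0.2095, # normoxia: dry-air oxygen fraction
  PX = 0.05,   # physioxia
  HX = 0.02    # hypoxia
)

#' Incubator gas environment
#'
#' Describes the gas phase above the culture media: the nominal (dry-gas)
#' oxygen fraction of the incubator setting, total pressure, and the partial
#' pressures of CO2 and water vapour that displace oxygen in a humidified
#' 5 percent CO2 incubator.  Dissolved oxygen at the media free surface
#' follows Henry's law with a solubility of 1.3 uM/mmHg at 37 C.
#'
#' @param label One of `"NX"` (normoxia, 20.95 percent dry gas), `"PX"`
#'   (physioxia, 5 percent), `"HX"` (hypoxia, 2 percent) or `"custom"`.
#' @param o2_fraction Nominal dry-gas oxygen fraction.  Defaults to the
#'   preset for `label`; required when `label = "custom"`.
#' @param total_pressure Total pressure in mmHg (sea level, 760).
#' @param p_co2 CO2 partial pressure in mmHg (5 percent CO2, 38).
#' @param p_h2o Water-vapour partial pressure in mmHg (75 percent
#'   humidity at 37 C, 47).
#' @param solubility Oxygen solubility of culture media in uM/mmHg (1.3).
#' @return An object of class `gas_env`.
#' @examples
#' nx <- gas_environment("NX")
#' dissolved_oxygen(nx)            # ~183.8 uM
#' percent_o2_equivalent(dissolved_oxygen(nx), nx)  # ~18.6 %O2
#' @export
gas_environment <- function(label = c("NX", "PX", "HX", "custom"),
                            o2_fraction = NULL,
                            total_pressure = 760,
                            p_co2 = 38,
                            p_h2o = 47,
                            solubility = 1.3) {
  label <- match.arg(label)
  if (is.null(o2_fraction)) {
    if (label == "custom")
      stop("`o2_fraction` must be given for a custom gas environment")
    o2_fraction <- .GAS_PRESETS[[label]]
  }
  env <- structure(
    list(label = label,
         o2_fraction = as.numeric(o2_fraction),
         total_pressure = as.numeric(total_pressure),
         p_co2 = as.numeric(p_co2),
         p_h2o = as.numeric(p_h2o),
         solubility = as.numeric(solubility)),
    class = "gas_env")
  validate_gas_env(env)
  env
}

validate_gas_env <- function(env) {
  stopifnot(inherits(env, "gas_env"))
  if (!(env$p_co2 >= 0 && env$p_h2o >= 0 &&
        env$p_co2 + env$p_h2o < env$total_pressure))
    stop("invalid gas environment: p_co2 + p_h2o must be below total pressure")
  if (env$o2_fraction < 0 || env$o2_fraction > 0.2095)
    stop("invalid gas environment: o2_fraction must lie in [0, 0.2095]")
  if (env$solubility <= 0)
    stop("invalid gas environment: solubility must be positive")
  invisible(env)
}

#' @export
print.gas_env <- function(x, ...) {
  cat(sprintf(
    "<gas_env> %s: %.4g%% O2 dry gas, %g mmHg (CO2 %g, H2O %g) -> %.1f uM dissolved\n",
    x$label, 100 * x$o2_fraction, x$total_pressure, x$p_co2, x$p_h2o,
    dissolved_oxygen(x)))
  invisible(x)
}

#' Dissolved-oxygen boundary concentration of an incubator setting
#'
#' Oxygen partial pressure in the humidified incubator gas is
#' `o2_fraction * (total_pressure - p_co2 - p_h2o)`; Henry's law converts it
#' to the dissolved concentration `solubility * pO2` that is imposed as the
#' fixed boundary condition at the media free surface.
#'
#' @param env A [gas_environment()].
#' @return Dissolved oxygen concentration in uM.
#' @export
dissolved_oxygen <- function(env) {
  validate_gas_env(env)
  po2 <- env$o2_fraction * (env$total_pressure - env$p_co2 - env$p_h2o)
  if (po2 < 0) stop("invalid gas environment: negative oxygen partial pressure")
  env$solubility * po2
}

#' Gas-phase percentage equivalent of a dissolved-oxygen concentration
#'
#' Back-converts a dissolved concentration (uM) to the gas-phase percentage
#' of total pressure whose equilibrium dissolved level equals the input:
#' `conc / (solubility * total_pressure / 100)`.  This is the "%O2" unit in
#' which culture oxygen levels are conventionally reported.
#'
#' @param concentration Dissolved oxygen in uM (vectorized).
#' @param env A [gas_environment()] supplying solubility and total pressure.
#' @return Oxygen level in %O2 units.
#' @export
percent_o2_equivalent <- function(concentration, env) {
  validate_gas_env(env)
  concentration / (env$solubility * env$total_pressure / 100)
}

#' Effective gas-phase oxygen percentage of an environment
#'
#' The humidity- and CO2-corrected oxygen percentage of total pressure,
#' i.e. `percent_o2_equivalent(dissolved_oxygen(env), env)` in closed form.
#'
#' @inheritParams dissolved_oxygen
#' @return Percentage of total pressure.
#' @export
effective_gas_percent <- function(env) {
  validate_gas_env(env)
  100 * env$o2_fraction *
    (env$total_pressure - env$p_co2 - env$p_h2o) / env$total_pressure
}
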