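# Post-processing: summary tables in the field's reporting units
# (%O2, mM, pH), spatial profiles, and the cell-surface series for 2D runs.

.REGION_NAME <- c("media", "construct")

# Volume-weighted stats of one per-cell field over a region.
.region_stats <- function(values, w, sel) {
  v <- values[sel]; ww <- w[sel]
  c(min = min(v), max = max(v), mean = sum(v * ww) / sum(ww))
}

#' Summarize a simulation result
#'
#' Extrema and volume-weighted averages of each solute per region (media /
#' construct) at the requested times, in the reporting conventions of the
#' field: oxygen dual-reported in uM and %O2 (gas-phase equivalent),
#' glucose and lactate in mM, pH in pH units.  For monolayer runs a
#' `cell_surface` region reports the concentrations at the vessel base,
#' with oxygen extrapolated through the half-cell to the surface itself.
#'
#' @param result A [run_transient()] result.
#' @param times Times (h) to summarize; defaults to the pre-exchange
#'   snapshot(s) and the final sample.
#' @return A long-format data.frame with columns `scenario`, `phenotype`,
#'   `o2_regime`, `glucose_regime`, `time_h`, `region`, `solute`, `stat`,
#'   `value`, `unit`.
#' @export
summarize_result <- function(result, times = NULL) {
  sc <- result$scenario
  mesh <- result$mesh
  if (is.null(times)) {
    ex <- sc$schedule$exchange_days * 24
    ex <- ex[ex <= max(result$times)]
    times <- unique(c(pmax(ex - 1 / 60, 0), max(result$times)))
  }
  w <- mesh$vol * mesh$count
  env <- sc$environment
  rows <- list()
  add <- function(time_h, region, solute, stat, value, unit)
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = sc$id, phenotype = sc$params$phenotype,
      o2_regime = sc$params$oxygen_regime,
      glucose_regime = sc$params$glucose_regime,
      time_h = time_h, region = region, solute = solute, stat = stat,
      value = value, unit = unit, stringsAsFactors = FALSE)
  for (tm in times) {
    st <- state_at(result, tm)
    for (reg in 1:2) {
      sel <- mesh$region == reg
      if (!any(sel)) next
      rn <- .REGION_NAME[reg]
      so <- .region_stats(st$o2, w, sel)
      sg <- .region_stats(st$glucose, w, sel)
      sl <- .region_stats(st$lactate, w, sel)
      sp <- .region_stats(st$ph, w, sel)
      for (stat in names(so)) {
        add(st$t, rn, "o2", stat, so[[stat]], "uM")
        add(st$t, rn, "o2", stat, percent_o2_equivalent(so[[stat]], env),
            "%O2")
        add(st$t, rn, "glucose", stat, sg[[stat]], "mM")
        add(st$t, rn, "lactate", stat, sl[[stat]], "mM")
        add(st$t, rn, "ph", stat, sp[[stat]], "pH")
      }
    }
    if (!is.null(mesh$mono)) {
      surf <- .surface_values(st, mesh, sc)
      add(st$t, "cell_surface", "o2", "point", surf$o2_uM, "uM")
      add(st$t, "cell_surface", "o2", "point",
          percent_o2_equivalent(surf$o2_uM, env), "%O2")
      add(st$t, "cell_surface", "glucose", "point", surf$glucose_mM, "mM")
      add(st$t, "cell_surface", "ph", "point", surf$ph, "pH")
    }
  }
  do.call(rbind, rows)
}

# Concentrations at the monolayer surface: bottom-cell values with oxygen
# (and glucose) extrapolated through the half-cell using the areal flux.
.surface_values <- function(state, mesh, scenario) {
  i <- mesh$mono$cell
  mil <- population(state$t / 24, mesh$mono$pop) * mesh$mono$area_cm2 / 1e6
  area_m2 <- mesh$mono$area_cm2 * 1e-4
  d_half <- mesh$vol[i] / area_m2 / 2                     # half cell height, m
  ro <- ocr(max(state$o2[i], 0), state$ph[i], scenario$params) * mil # nmol/h
  rg <- gcr(max(state$glucose[i], 0), scenario$params) * mil
  # nmol/h over area, through D (m^2/h): uM and mM deficits
  d_o2 <- ro / area_m2 * d_half / mesh$D[i, "o2"] * 1e-6
  d_gl <- rg / area_m2 * d_half / mesh$D[i, "glucose"] * 1e-9
  list(o2_uM = max(state$o2[i] - d_o2, 0),
       glucose_mM = max(state$glucose[i] - d_gl, 0),
       ph = state$ph[i])
}

#' Cell-surface concentration series of a monolayer run
#'
#' @param result A monolayer [run_transient()] result.
#' @return data.frame with `time_h`, `o2_uM`, `o2_percent`, `glucose_mM`,
#'   `ph`, and the boundary deficit `o2_drop_percent`
#'   (incubator-equivalent %O2 minus cell-surface %O2).
#' @export
surface_series <- function(result) {
  mesh <- result$mesh
  if (is.null(mesh$mono)) stop("surface series requires a monolayer scenario")
  env <- result$scenario$environment
  bc_pct <- percent_o2_equivalent(mesh$bc_o2, env)
  out <- lapply(seq_along(result$times), function(k) {
    st <- state_at(result, result$times[k], tol = Inf)
    sv <- .surface_values(st, mesh, result$scenario)
    data.frame(time_h = st$t, o2_uM = sv$o2_uM,
               o2_percent = percent_o2_equivalent(sv$o2_uM, env),
               glucose_mM = sv$glucose_mM, ph = sv$ph)
  })
  out <- do.call(rbind, out)
  out$o2_drop_percent <- bc_pct - out$o2_percent
  out
}

#' Spatial concentration profile at a sampled time
#'
#' Axial profiles run from the vessel base (position 0) to the media free
#' surface along the symmetry axis; radial profiles run outward at the
#' construct mid-height (axisymmetric meshes) or through the bead shells
#' (compartment meshes).
#'
#' @param result A [run_transient()] result.
#' @param time Time in hours (nearest sample).
#' @param axis `"axial"` or `"radial"`.
#' @return data.frame with `position_mm`, `region`, `o2_uM`, `o2_percent`,
#'   `glucose_mM`, `lactate_mM`, `ph`.
#' @export
extract_profile <- function(result, time, axis = c("axial", "radial")) {
  axis <- match.arg(axis)
  mesh <- result$mesh
  st <- state_at(result, time, tol = Inf)
  env <- result$scenario$environment
  if (mesh$symmetry == "planar1D") {
    sel <- seq_len(mesh$n); pos <- mesh$coords$z
  } else if (mesh$symmetry == "axisymmetric2D") {
    g <- mesh$geom
    if (axis == "axial") {
      sel <- stats::na.omit(g$idx[1L, ]); pos <- mesh$coords$z[sel]
    } else {
      zmid <- g$construct_extent_z / 2
      jz <- which.min(abs(g$z - zmid))
      sel <- stats::na.omit(g$idx[, jz]); pos <- mesh$coords$r[sel]
    }
  } else { # compartment: bead shells then media column
    if (axis == "radial") {
      sel <- which(mesh$region == 2L); pos <- mesh$coords$r[sel]
    } else {
      sel <- which(mesh$region == 1L); pos <- mesh$coords$z[sel]
    }
  }
  sel <- as.integer(sel)
  data.frame(position_mm = pos * 1e3,
             region = .REGION_NAME[mesh$region[sel]],
             o2_uM = st$o2[sel],
             o2_percent = percent_o2_equivalent(st$o2[sel], env),
             glucose_mM = st$glucose[sel],
             lactate_mM = st$lactate[sel],
             ph = st$ph[sel])
}

#' Scalar summary statistic of a simulation result
#'
#' Convenience accessor for single reported quantities, e.g. the
#' construct-minimum oxygen in %O2 at the day-3 pre-exchange snapshot.
#'
#' @param result A [run_transient()] result.
#' @param time Time in hours (nearest sample).
#' @param solute `"o2"`, `"glucose"`, `"lactate"` or `"ph"`.
#' @param stat `"min"`, `"max"` or `"mean"` (volume-weighted).
#' @param region `"construct"`, `"media"` or `"all"`.
#' @param unit `"native"` (uM / mM / pH) or `"percent"` (%O2, oxygen only).
#' @return A single numeric value.
#' @export
microenv_stat <- function(result, time, solute = "o2", stat = "min",
                          region = "construct", unit = "native") {
  st <- state_at(result, time, tol = Inf)
  mesh <- result$mesh
  sel <- switch(region,
                construct = mesh$region == 2L,
                media = mesh$region == 1L,
                all = rep(TRUE, mesh$n),
                stop("unknown region '", region, "'"))
  if (!any(sel)) stop("region '", region, "' is empty in this mesh")
  v <- st[[solute]][sel]
  w <- (mesh$vol * mesh$count)[sel]
  x <- switch(stat, min = min(v), max = max(v), mean = sum(v * w) / sum(w),
              stop("unknown stat '", stat, "'"))
  if (unit == "percent") {
    if (solute != "o2") stop("percent unit applies to oxygen only")
    x <- percent_o2_equivalent(x, result$scenario$environment)
  }
  x
}

#' Total solute inventory of a state or sampled time
#'
#' Sum of concentration x cell volume (x bead multiplicity), used by the
#' mass-conservation diagnostics: between exchanges,
#' `inventory(t) + consumed(t)` is constant for glucose, and
#' `inventory(t) - produced(t)` for lactate.
#'
#' @param result A [run_transient()] result.
#' @param time Time in hours (nearest sample).
#' @param solute `"o2"` (uM m^3), `"glucose"` or `"lactate"` (mM m^3).
#' @return Inventory in concentration x m^3 units.
#' @export
solute_inventory <- function(result, time, solute = "glucose") {
  st <- state_at(result, time, tol = Inf)
  sum(st[[solute]] * result$mesh$vol * result$mesh$count)
}

#' @export
plot.sim_result <- function(x, solute = "o2", ...) {
  mesh <- x$mesh
  w <- mesh$vol * mesh$count
  reg <- if (any(mesh$region == 2L)) mesh$region == 2L else mesh$region == 1L
  f <- x$fields[[solute]]
  mn <- apply(f[reg, , drop = FALSE], 2, min)
  av <- apply(f[reg, , drop = FALSE], 2, function(v)
    sum(v * w[reg]) / sum(w[reg]))
  ylab <- switch(solute, o2 = "oxygen (uM)", ph = "pH",
                 paste(solute, "(mM)"))
  graphics::plot(x$times, av, type = "l", xlab = "time (h)", ylab = ylab,
                 ylim = range(c(mn, av)), ...)
  graphics::lines(x$times, mn, lty = 2)
  graphics::legend("bottomleft", legend = c("region mean", "region min"),
                   lty = 1:2, bty = "n")
  invisible(x)
}
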