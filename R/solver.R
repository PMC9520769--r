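# Transient and steady-state reaction-diffusion solvers.
#
# Method of lines: the finite-volume diffusion operators are assembled as
# sparse matrices (dC/dt = A C + b) and the Michaelis-Menten metabolic
# sources are added cell-locally; deSolve's lsodes (stiff, sparse BDF)
# integrates the coupled system with media exchanges applied as
# instantaneous events.  Concentrations entering the rate laws are clamped
# at zero so sources vanish with the substrate (positivity preserving).
# Four auxiliary states integrate total oxygen consumption, glucose
# consumption, lactate production and boundary oxygen influx for the mass-
# conservation and flux-balance diagnostics.

.solver_parms <- function(mesh, scenario, mode) {
  ops <- assemble_ops(mesh)
  n <- mesh$n
  ic <- which(mesh$region == 2L & mesh$rho > 0)
  list(n = n, ops = ops, ic = ic, rho = mesh$rho, vol = mesh$vol,
       count = mesh$count, media = which(mesh$region == 1L),
       params = scenario$params, buffer = scenario$buffer,
       bc_o2 = mesh$bc_o2, glucose_fresh = scenario$glucose_mM,
       mono = mesh$mono, mode = mode,
       dir = ops$o2$dirichlet)
}

.rhs <- function(t, y, p) {
  n <- p$n
  i1 <- seq_len(n)
  o2r <- y[i1]; glr <- y[n + i1]; lar <- y[2L * n + i1]
  o2 <- pmax(o2r, 0); glc <- pmax(glr, 0); lac <- pmax(lar, 0)
  ph <- ph_from_lactate(lac, p$buffer)
  do2 <- as.numeric(p$ops$o2$A %*% o2r) + p$ops$o2$b
  if (p$mode == "full") {
    dgl <- as.numeric(p$ops$glucose$A %*% glr) + p$ops$glucose$b
    dla <- as.numeric(p$ops$lactate$A %*% lar) + p$ops$lactate$b
  } else {
    dgl <- dla <- numeric(n)
  }
  c_o2 <- c_gl <- p_la <- 0
  if (length(p$ic)) {
    i <- p$ic
    ro <- ocr(o2[i], ph[i], p$params) * p$rho[i]            # uM/h
    do2[i] <- do2[i] - ro
    c_o2 <- sum(ro * p$vol[i] * p$count[i])                 # uM m^3/h
    if (p$mode == "full") {
      rg <- gcr(glc[i], p$params) * p$rho[i] * 1e-3         # mM/h
      rl <- lpr(glc[i], ph[i], p$params) * p$rho[i] * 1e-3
      dgl[i] <- dgl[i] - rg
      dla[i] <- dla[i] + rl
      c_gl <- sum(rg * p$vol[i] * p$count[i])               # mM m^3/h
      p_la <- sum(rl * p$vol[i] * p$count[i])
    }
  }
  if (!is.null(p$mono)) {
    i <- p$mono$cell
    mil <- population(t / 24, p$mono$pop) * p$mono$area_cm2 / 1e6
    vol_ml <- p$vol[i] * 1e6
    ro <- ocr(o2[i], ph[i], p$params) * mil / vol_ml        # uM/h
    do2[i] <- do2[i] - ro
    c_o2 <- c_o2 + ro * p$vol[i]
    if (p$mode == "full") {
      rg <- gcr(glc[i], p$params) * mil / vol_ml * 1e-3     # mM/h
      rl <- lpr(glc[i], ph[i], p$params) * mil / vol_ml * 1e-3
      dgl[i] <- dgl[i] - rg
      dla[i] <- dla[i] + rl
      c_gl <- c_gl + rg * p$vol[i]
      p_la <- p_la + rl * p$vol[i]
    }
  }
  influx <- sum(p$dir$g * (p$dir$value - o2r[p$dir$cells]))  # uM m^3/h
  list(c(do2, dgl, dla, c_o2, c_gl, p_la, influx))
}

.exchange_event <- function(t, y, p) {
  n <- p$n
  m <- p$media
  y[m] <- p$bc_o2
  if (p$mode == "full") {
    y[n + m] <- p$glucose_fresh
    y[2L * n + m] <- 0
  }
  y
}

.initial_state <- function(mesh, scenario) {
  c(rep(mesh$bc_o2, mesh$n), rep(scenario$glucose_mM, mesh$n),
    rep(0, mesh$n), numeric(4))
}

.default_times <- function(scenario) {
  horizon <- scenario$schedule$horizon_days * 24
  ex <- scenario$schedule$exchange_days * 24
  ex <- ex[ex <= horizon]
  tt <- c(seq(0, horizon, length.out = 85), ex, pmax(ex - 1 / 60, 0))
  sort(unique(round(tt, 10)))
}

#' Transient coupled reaction-diffusion simulation of a scenario
#'
#' Integrates oxygen, glucose and lactate transport with cell metabolism
#' over the scenario horizon, applying media exchanges as instantaneous
#' resets of the media region.  Monolayer scenarios drive an areal sink at
#' the vessel base that follows the (capped) exponential population;
#' 3D constructs consume/produce volumetrically at constant density.
#'
#' @param scenario A [culture_scenario()].
#' @param mesh Optional pre-built [build_mesh()] result.
#' @param times Output times in hours; defaults to ~85 samples over the
#'   horizon plus each exchange time and the snapshot one minute before it.
#' @param mode `"full"` couples all three solutes; `"oxygen_only"` holds
#'   glucose and lactate at fresh-media values (pH stays at the fresh
#'   value), the configuration used for steady-state verification.
#' @param resolution Mesh resolution used when `mesh` is `NULL`.
#' @param rtol,atol Relative/absolute tolerances passed to the stiff
#'   integrator (`atol` defaults to 1e-3 uM for oxygen, 1e-6 mM for
#'   glucose and lactate).
#' @return An object of class `sim_result`: sampled concentration fields
#'   (`fields$o2` in uM, `fields$glucose` and `fields$lactate` in mM,
#'   `fields$ph`) as cell-by-time matrices, the sample `times` (h), the
#'   mesh, the scenario, and `aux`, the running totals of consumption,
#'   production and boundary influx used by the conservation diagnostics.
#' @export
run_transient <- function(scenario, mesh = NULL, times = NULL,
                          mode = c("full", "oxygen_only"),
                          resolution = 40, rtol = 1e-6, atol = NULL) {
  mode <- match.arg(mode)
  if (is.null(mesh)) mesh <- build_mesh(scenario, resolution)
  if (is.null(times)) times <- .default_times(scenario)
  p <- .solver_parms(mesh, scenario, mode)
  n <- mesh$n
  y0 <- .initial_state(mesh, scenario)
  if (is.null(atol))
    atol <- c(rep(1e-3, n), rep(1e-6, 2L * n), rep(1e-9, 4))
  ex_h <- scenario$schedule$exchange_days * 24
  ex_h <- ex_h[ex_h > min(times) & ex_h <= max(times)]
  ev <- if (length(ex_h))
    list(func = .exchange_event, time = ex_h) else NULL
  out <- deSolve::ode(y = y0, times = times, func = .rhs, parms = p,
                      method = "lsodes", events = ev,
                      rtol = rtol, atol = atol, maxsteps = 10000)
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times))
    stop("solver failed to converge (istate = ", istate,
         ", completed ", nrow(out), "/", length(times), " output times)")
  tt <- out[, 1]
  grab <- function(k) unname(t(out[, 1 + (k - 1L) * n + seq_len(n),
                                   drop = FALSE]))
  o2 <- grab(1); glc <- grab(2); lac <- grab(3)
  worst <- min(o2, glc, lac)
  if (worst < -0.5)
    stop("positivity violation: concentration reached ", signif(worst, 3))
  o2 <- pmax(o2, 0); glc <- pmax(glc, 0); lac <- pmax(lac, 0)
  if (mode == "oxygen_only") {
    glc[] <- scenario$glucose_mM
    lac[] <- 0
  }
  aux <- data.frame(time_h = tt,
                    o2_consumed = out[, 3L * n + 2],
                    glucose_consumed = out[, 3L * n + 3],
                    lactate_produced = out[, 3L * n + 4],
                    o2_influx = out[, 3L * n + 5])
  structure(list(scenario = scenario, mesh = mesh, times = tt, mode = mode,
                 fields = list(o2 = o2, glucose = glc, lactate = lac,
                               ph = ph_from_lactate(lac, scenario$buffer)),
                 aux = aux),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %s: %d cells x %d times over %.3g h (%s mode)\n",
    x$scenario$id, x$mesh$n, length(x$times), max(x$times), x$mode))
  invisible(x)
}

#' Apply an instantaneous media exchange to a field state
#'
#' Media-region cells are reset to fresh values (scenario glucose, zero
#' lactate, incubator-equilibrated dissolved oxygen); construct-region
#' cells are untouched.  The operation is idempotent.
#'
#' @param state A `field_state` (see [state_at()] / [steady_state()]).
#' @param scenario The owning [culture_scenario()].
#' @param mesh The mesh the state lives on (defaults to `state$mesh`).
#' @return The exchanged `field_state`.
#' @export
apply_media_exchange <- function(state, scenario, mesh = state$mesh) {
  m <- which(mesh$region == 1L)
  state$o2[m] <- mesh$bc_o2
  state$glucose[m] <- scenario$glucose_mM
  state$lactate[m] <- 0
  state$ph <- ph_from_lactate(state$lactate, scenario$buffer)
  state
}

#' Extract the field state at a sampled time
#'
#' @param result A [run_transient()] result.
#' @param time Requested time in hours; matched to the nearest sample
#'   (which must lie within `tol` hours).
#' @param tol Matching tolerance in hours.
#' @return A `field_state`: per-cell `o2` (uM), `glucose`/`lactate` (mM),
#'   `ph`, plus the time, mesh and scenario.
#' @export
state_at <- function(result, time, tol = 0.51) {
  k <- which.min(abs(result$times - time))
  if (abs(result$times[k] - time) > tol)
    stop("no sample within ", tol, " h of t = ", time)
  structure(list(t = result$times[k],
                 o2 = result$fields$o2[, k],
                 glucose = result$fields$glucose[, k],
                 lactate = result$fields$lactate[, k],
                 ph = result$fields$ph[, k],
                 mesh = result$mesh, scenario = result$scenario),
            class = "field_state")
}

#' Steady-state oxygen field of a scenario
#'
#' Solves the nonlinear steady diffusion-consumption balance for oxygen
#' with glucose and lactate held at fresh-media values (pH at the fresh
#' value), by damped Newton iteration on the finite-volume system.  For
#' monolayer scenarios the population is evaluated at `at_day`
#' (defaulting to the horizon, i.e. the capped population).
#'
#' @inheritParams run_transient
#' @param at_day Population time used for monolayer scenarios (days).
#' @param tol Convergence tolerance: the residual infinity-norm relative
#'   to the boundary-exchange scale.
#' @param max_iter Maximum Newton iterations.
#' @return A `field_state` with the converged oxygen field (glucose and
#'   lactate at fresh values) and attribute `"residual"`.
#' @export
steady_state <- function(scenario, mesh = NULL, resolution = 40,
                         at_day = NULL, tol = 1e-8, max_iter = 60) {
  if (is.null(mesh)) mesh <- build_mesh(scenario, resolution)
  p <- .solver_parms(mesh, scenario, "oxygen_only")
  n <- mesh$n
  ph_fresh <- scenario$buffer$ph_fresh
  lin <- ocr_linearization(ph_fresh, scenario$params)
  vmax_eff <- p$rho * lin$vmax_eff # uM/h at saturation
  if (!is.null(p$mono)) {
    if (is.null(at_day)) at_day <- scenario$schedule$horizon_days
    mil <- population(at_day, p$mono$pop) * p$mono$area_cm2 / 1e6
    vmax_eff[p$mono$cell] <- vmax_eff[p$mono$cell] +
      lin$vmax_eff * mil / (p$vol[p$mono$cell] * 1e6)
  }
  A <- p$ops$o2$A; b <- p$ops$o2$b
  km <- lin$km_eff[1]
  scale <- max(abs(b), 1e-12)
  C <- rep(mesh$bc_o2, n)
  res <- Inf
  for (it in seq_len(max_iter)) {
    Cc <- pmax(C, 0)
    s <- -vmax_eff * Cc / (km + Cc)
    FF <- as.numeric(A %*% C) + b + s
    res <- max(abs(FF)) / scale
    if (res < tol) break
    ds <- -vmax_eff * km / (km + Cc)^2
    J <- A + Matrix::Diagonal(n, x = ds)
    dC <- as.numeric(Matrix::solve(J, -FF))
    alpha <- 1
    while (any(C + alpha * dC < -1e-9 * mesh$bc_o2) && alpha > 1e-4)
      alpha <- alpha / 2
    C <- C + alpha * dC
  }
  if (res >= tol)
    stop("steady-state Newton iteration did not converge: residual ",
         signif(res, 3), " after ", max_iter, " iterations")
  C <- pmax(C, 0)
  st <- structure(list(t = Inf, o2 = C,
                       glucose = rep(scenario$glucose_mM, n),
                       lactate = rep(0, n),
                       ph = rep(ph_from_lactate(0, scenario$buffer), n),
                       mesh = mesh, scenario = scenario),
                  class = "field_state")
  attr(st, "residual") <- res
  st
}

#' Reduced-order multi-bead culture simulation
#'
#' Each of the N identical beads is solved as a spherically symmetric
#' shell mesh; all beads couple to a single 1D media column through a
#' film/spreading conductance (the access resistance `1/(4 pi D R)` of a
#' sphere in media, in series with the outer half-shell).  This
#' compartment approximation replaces a full 3D multi-bead layout: it
#' conserves mass exactly and reproduces the single-bead axisymmetric
#' model closely, and depletion/acidification increase strictly with N.
#'
#' @inheritParams run_transient
#' @return A `sim_result` on the compartment mesh.
#' @export
compartment_multibead <- function(scenario, times = NULL,
                                  mode = c("full", "oxygen_only"),
                                  resolution = 40, rtol = 1e-6, atol = NULL) {
  mesh <- .mesh_multibead(scenario, resolution)
  run_transient(scenario, mesh = mesh, times = times,
                mode = match.arg(mode), rtol = rtol, atol = atol)
}
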