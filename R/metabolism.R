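# Cell-level rate laws: oxygen consumption (OCR), glucose consumption (GCR),
# lactate production (LPR), the lactate -> pH buffer map, and 2D
# proliferation kinetics.  All per-cell rates are in nmol/10^6 cells/h.

# Compiled metabolic constants by external boundary regime.  GCR/LPR are
# averages over species and degeneration stage; OCR splits into a lower
# (animal + healthy human) and a higher (degenerated human) phenotype.
.GCR_VMAX <- c(NX = 143, PX = 103, HX = 165)   # nmol/10^6 cells/h
.LPR_VMAX <- c(NX = 207, PX = 168, HX = 296)   # explicit LPR table (optional)
.LAC_GLUC_RATIO <- c(NX = 1.4, PX = 1.6, HX = 1.8)
.OCR_VMAX <- c(animal = 17, degenerated = 62)  # nmol/10^6 cells/h

# pH multiplier anchors for lactate production: measured rates fall from
# ~200 nmol/10^6 cells/h at pH 7.4 to ~150 at pH 6.7 and ~50 at pH 6.2.
.LPR_PH_ANCHORS <- cbind(ph = c(6.2, 6.7, 7.4), mult = c(0.25, 0.75, 1.0))

# Default lactate -> pH slope (pH units per mM lactate).  Calibrated once
# against the transient bead model (8e6 cells/ml, HX + LG, minimum pH 7.0 at
# the day-3 pre-exchange snapshot) and frozen; see the methods vignette.
NP_PH_SLOPE_DEFAULT <- 0.141

#' Metabolic parameter set for one boundary-condition regime
#'
#' Bundles the Michaelis-Menten constants used by [ocr()], [gcr()] and
#' [lpr()] for a given oxygen regime (NX/PX/HX), media glucose regime
#' (LG/HG) and cell phenotype.  Glycolytic constants do not differ
#' detectably between low- and high-glucose media, so both glucose regimes
#' default to the same compiled values; any field can be overridden.
#'
#' @param oxygen_regime `"NX"`, `"PX"` or `"HX"`.
#' @param glucose_regime `"LG"` (5.5 mM) or `"HG"` (25 mM).
#' @param phenotype `"animal"` (animal + healthy human, OCR Vmax 17) or
#'   `"degenerated"` (degenerated human, OCR Vmax 62).
#' @param ocr_vmax,ocr_km,ocr_ph_offset,ocr_ph_ref Oxygen-consumption
#'   constants: Vmax (nmol/10^6 cells/h), Km (uM), the pH at which
#'   respiration ceases, and the reference pH at which Vmax was measured.
#' @param gcr_vmax,gcr_km Glucose-consumption Vmax (nmol/10^6 cells/h) and
#'   Km (mM; glycolysis becomes rate-limited at ~2 mM).
#' @param lac_gluc_ratio Moles of lactate produced per mole of glucose
#'   consumed; rises as external oxygen falls (NX 1.4, PX 1.6, HX 1.8).
#' @param lpr_vmax Explicit lactate-production Vmax used when
#'   `lpr_mode = "table"`.
#' @param lpr_mode `"ratio"` computes LPR as `lac_gluc_ratio * GCR` (the
#'   default, capturing rate-limited glycolysis); `"table"` uses the
#'   compiled LPR Vmax directly.
#' @param lpr_ph_anchors Two-column matrix of (pH, multiplier) pairs,
#'   non-decreasing in pH, through which the LPR pH response is
#'   piecewise-linearly interpolated.
#' @param ocr_ph_form `"scaled"` (default) applies the pH factor of the
#'   respiration law literally, `Vmax * (pH - offset)`, with
#'   `Km * (pH - offset)` in the denominator, so the realized saturating
#'   rate at the reference pH 7.4 is `2.45 * Vmax`; `"normalized"` divides
#'   both pH terms by `(ref - offset)` so the tabulated Vmax is itself the
#'   saturating rate at pH 7.4.  See [ocr()].
#' @return An object of class `metabolic_params`.
#' @examples
#' p <- metabolic_params("NX", "LG", "animal")
#' ocr(1e6, 7.4, p)   # saturating rate = 17
#' gcr(2, p)          # half-saturation = 71.5
#' @export
metabolic_params <- function(oxygen_regime = c("NX", "PX", "HX"),
                             glucose_regime = c("LG", "HG"),
                             phenotype = c("animal", "degenerated"),
                             ocr_vmax = NULL,
                             ocr_km = 12,
                             ocr_ph_offset = 4.95,
                             ocr_ph_ref = 7.4,
                             gcr_vmax = NULL,
                             gcr_km = 2,
                             lac_gluc_ratio = NULL,
                             lpr_vmax = NULL,
                             lpr_mode = c("ratio", "table"),
                             lpr_ph_anchors = .LPR_PH_ANCHORS,
                             ocr_ph_form = c("scaled", "normalized")) {
  oxygen_regime <- match.arg(oxygen_regime)
  glucose_regime <- match.arg(glucose_regime)
  phenotype <- match.arg(phenotype)
  lpr_mode <- match.arg(lpr_mode)
  ocr_ph_form <- match.arg(ocr_ph_form)
  if (is.null(ocr_vmax)) ocr_vmax <- unname(.OCR_VMAX[phenotype])
  if (is.null(gcr_vmax)) gcr_vmax <- unname(.GCR_VMAX[oxygen_regime])
  if (is.null(lac_gluc_ratio))
    lac_gluc_ratio <- unname(.LAC_GLUC_RATIO[oxygen_regime])
  if (is.null(lpr_vmax)) lpr_vmax <- unname(.LPR_VMAX[oxygen_regime])
  p <- structure(
    list(oxygen_regime = oxygen_regime,
         glucose_regime = glucose_regime,
         phenotype = phenotype,
         ocr_vmax = as.numeric(ocr_vmax),
         ocr_km = as.numeric(ocr_km),
         ocr_ph_offset = as.numeric(ocr_ph_offset),
         ocr_ph_ref = as.numeric(ocr_ph_ref),
         gcr_vmax = as.numeric(gcr_vmax),
         gcr_km = as.numeric(gcr_km),
         lac_gluc_ratio = as.numeric(lac_gluc_ratio),
         lpr_vmax = as.numeric(lpr_vmax),
         lpr_mode = lpr_mode,
         lpr_ph_anchors = lpr_ph_anchors,
         ocr_ph_form = ocr_ph_form),
    class = "metabolic_params")
  validate_metabolic_params(p)
  p
}

validate_metabolic_params <- function(p) {
  stopifnot(inherits(p, "metabolic_params"))
  if (!(p$ocr_vmax > 0 && p$ocr_km > 0 && p$gcr_vmax > 0 && p$gcr_km > 0 &&
        p$lpr_vmax > 0))
    stop("all Vmax and Km values must be positive")
  if (p$lac_gluc_ratio < 1 || p$lac_gluc_ratio > 2)
    stop("lac:gluc ratio must lie in [1, 2]")
  a <- p$lpr_ph_anchors
  if (!is.matrix(a) || ncol(a) != 2 || nrow(a) < 2 ||
      is.unsorted(a[, 1]) || is.unsorted(a[, 2]))
    stop("lpr_ph_anchors must be non-decreasing (pH, multiplier) pairs")
  if (p$ocr_ph_ref <= p$ocr_ph_offset)
    stop("ocr_ph_ref must exceed ocr_ph_offset")
  invisible(p)
}

#' @export
print.metabolic_params <- function(x, ...) {
  cat(sprintf(
    "<metabolic_params> %s+%s, %s: OCR Vmax %g (Km %g uM), GCR Vmax %g (Km %g mM), lac:gluc %g (%s LPR)\n",
    x$oxygen_regime, x$glucose_regime, x$phenotype, x$ocr_vmax, x$ocr_km,
    x$gcr_vmax, x$gcr_km, x$lac_gluc_ratio, x$lpr_mode))
  invisible(x)
}

#' Oxygen consumption rate
#'
#' pH- and oxygen-dependent Michaelis-Menten respiration.  In the default
#' `"scaled"` form the pH factor enters literally,
#' `Vmax * (pH - offset) * O2 / (Km * (pH - offset) + O2)`
#' with offset 4.95, so respiration vanishes at pH 4.95 and the realized
#' saturating rate at the reference pH 7.4 is `(7.4 - 4.95) * Vmax =
#' 2.45 * Vmax` (the convention of the lineage of disc-cell respiration
#' models these constants come from, and the one that reproduces the
#' reported culture oxygen minima).  In the `"normalized"` form both pH
#' terms are divided by `(ref - offset)` so the tabulated Vmax is itself
#' the saturating rate at pH 7.4 and Km stays at its nominal value.
#' Rates are clamped at zero.
#'
#' @param o2 Local dissolved oxygen in uM (vectorized, non-negative).
#' @param ph Local pH (vectorized).
#' @param params A [metabolic_params()] object.
#' @return Rate in nmol/10^6 cells/h.
#' @export
ocr <- function(o2, ph, params) {
  if (any(o2 < 0)) stop("oxygen concentration must be non-negative")
  lin <- ocr_linearization(ph, params)
  pmax(lin$vmax_eff * o2 / (lin$km_eff + o2), 0)
}

# Effective (Vmax, Km) of the respiration law at a given pH: the rate is
# vmax_eff * O2 / (km_eff + O2).  Shared by ocr() and the steady-state
# Newton solver.
ocr_linearization <- function(ph, params) {
  phf <- pmax(ph - params$ocr_ph_offset, 0)
  if (params$ocr_ph_form == "scaled") {
    list(vmax_eff = params$ocr_vmax * phf,
         km_eff = pmax(params$ocr_km * phf, 1e-12))
  } else {
    norm <- params$ocr_ph_ref - params$ocr_ph_offset
    list(vmax_eff = params$ocr_vmax * phf / norm,
         km_eff = rep_len(params$ocr_km, length(phf)))
  }
}

#' Glucose consumption rate
#'
#' Michaelis-Menten glucose uptake `Vmax * C/(Km + C)`, rate-limited below
#' ~2 mM and saturating toward the regime Vmax in glucose-replete media.
#'
#' @param glucose Local glucose in mM (vectorized, non-negative).
#' @inheritParams ocr
#' @return Rate in nmol/10^6 cells/h.
#' @export
gcr <- function(glucose, params) {
  if (any(glucose < 0)) stop("glucose concentration must be non-negative")
  params$gcr_vmax * glucose / (params$gcr_km + glucose)
}

.lpr_ph_multiplier <- function(ph, anchors) {
  stats::approx(anchors[, 1], anchors[, 2], xout = ph, rule = 2)$y
}

#' Lactate production rate
#'
#' By default lactate production tracks instantaneous glucose consumption
#' through the regime lac:gluc ratio (glycolysis rate-limited together with
#' glucose uptake), modulated by a piecewise-linear pH response anchored at
#' (7.4, 1.0), (6.7, 0.75) and (6.2, 0.25) to capture the measured collapse
#' of lactate production in acidic media.  With `lpr_mode = "table"` the
#' compiled LPR Vmax replaces `ratio * gcr_vmax`.
#'
#' @inheritParams gcr
#' @param ph Local pH (vectorized).
#' @return Rate in nmol/10^6 cells/h.
#' @export
lpr <- function(glucose, ph, params) {
  m <- .lpr_ph_multiplier(ph, params$lpr_ph_anchors)
  base <- if (params$lpr_mode == "ratio")
    params$lac_gluc_ratio * gcr(glucose, params)
  else
    params$lpr_vmax * glucose / (params$gcr_km + glucose)
  base * m
}

#' Media buffering model: pH as a function of accumulated lactate
#'
#' Fresh media sits at `ph_fresh`; pH falls linearly with lactate
#' concentration at `slope` pH units per mM down to `floor`.  The default
#' slope is a frozen constant calibrated once against the transient bead
#' model (see the methods vignette); set `slope = 0` to pin pH at the fresh
#' value (useful for oxygen-only verification runs).
#'
#' @param ph_fresh pH of fresh media (7.4).
#' @param slope pH units lost per mM lactate (>= 0).
#' @param floor Minimum pH reached under heavy acidification.
#' @return An object of class `buffer_model`.
#' @export
buffer_model <- function(ph_fresh = 7.4, slope = NP_PH_SLOPE_DEFAULT,
                         floor = 6.0) {
  if (slope < 0) stop("buffer slope must be non-negative")
  if (floor > ph_fresh) stop("buffer floor cannot exceed the fresh-media pH")
  structure(list(ph_fresh = ph_fresh, slope = slope, floor = floor),
            class = "buffer_model")
}

#' pH of media containing a given lactate concentration
#'
#' @param lactate Lactate in mM (vectorized).
#' @param buffer A [buffer_model()].
#' @return pH, monotone non-increasing in lactate.
#' @export
ph_from_lactate <- function(lactate, buffer) {
  pmax(buffer$ph_fresh - buffer$slope * pmax(lactate, 0), buffer$floor)
}

#' Monolayer cell population
#'
#' Areal seeding and first-order growth for 2D expansion: cells/cm^2 grow
#' exponentially at rate `growth_rate` from `initial_count` and are capped
#' at `confluency_cap` (the 80 percent-confluency endpoint, ~28571
#' cells/cm^2 for NP cells).
#'
#' @param initial_count Seeding density in cells/cm^2.
#' @param growth_rate Exponential growth constant k in 1/day.
#' @param confluency_cap Areal density cap in cells/cm^2.
#' @return An object of class `cell_population`.
#' @export
cell_population <- function(initial_count = 5000, growth_rate = 0.348,
                            confluency_cap = 28571) {
  if (initial_count < 0 || growth_rate < 0 || confluency_cap <= 0)
    stop("population parameters must be non-negative (cap positive)")
  structure(list(initial_count = initial_count, growth_rate = growth_rate,
                 confluency_cap = confluency_cap),
            class = "cell_population")
}

#' Population size at time t
#'
#' `N(t) = min(N0 * exp(k t), cap)` in cells/cm^2.
#'
#' @param t Time in days (vectorized, >= 0).
#' @param pop A [cell_population()].
#' @return Areal density in cells/cm^2.
#' @export
population <- function(t, pop) {
  if (any(t < 0)) stop("time must be non-negative")
  pmin(pop$initial_count * exp(pop$growth_rate * t), pop$confluency_cap)
}

#' Exponential growth rate from an observed expansion
#'
#' `k = ln(Nt/N0) / t`, the closed form linking a population doubling
#' observation to the first-order growth constant.
#'
#' @param N0,Nt Initial and final cell numbers (positive).
#' @param t Elapsed time in days (positive).
#' @return Growth rate k in 1/day.
#' @examples
#' growth_rate_from_doubling(5000, 28571, 5)  # ~0.348
#' @export
growth_rate_from_doubling <- function(N0, Nt, t) {
  if (any(N0 <= 0) || any(Nt <= 0) || any(t <= 0))
    stop("N0, Nt and t must be positive")
  log(Nt / N0) / t
}
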