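# Cross-sectional equilibrium of a uniform cylindrical segment and the six
# reported geometric/mechanical metrics.

#' Thin-wall (Laplace) mean circumferential stress
#'
#' @param P luminal pressure (mmHg).
#' @param a inner radius (mm).
#' @param h wall thickness (mm).
#' @return mean circumferential stress P*a/h (kPa).
#' @export
laplace_stress <- function(P, a, h) {
  if (any(h <= 0)) stop("thickness must be > 0")
  mmHg_to_kPa(P) * a / h
}

# Equilibrium residual for the elastic problem: mixture circumferential
# stress minus the supported Laplace demand.  `support` is the perivascular
# support fraction calibrated at the in-vivo state (see init_homeostatic).
.elastic_residual <- function(lt, lz, comp, P_kPa, par, support) {
  m <- .mix_mech(lt, lz, comp, P_kPa, par)
  m$sig[["t"]] - support * P_kPa * m$a / m$h
}

#' Solve the elastic state of a vessel with frozen composition
#'
#' Root-finds the mixture circumferential stretch such that the membrane
#' equilibrium sigma_tt = support * P * a / h holds, with incompressibility
#' linking current geometry (a, h) to the stretches.  The composition
#' (referential masses, insulted moduli, natural configurations) is frozen,
#' so the response is purely elastic, e.g. a diastolic unloading of an
#' equilibrated growth-and-remodelling state.
#'
#' @param state a \code{gr_state} carrying the frozen composition.
#' @param pressure target luminal pressure (mmHg).
#' @param lambda_z fixed axial stretch (default: the state's).
#' @param support perivascular support fraction; defaults to the value stored
#'   in \code{state$support} (set by [init_homeostatic()]), else 1.
#' @param tol absolute residual tolerance (kPa); default 1e-9 times the
#'   homeostatic stress scale.
#' @return a \code{gr_state} at the requested pressure, with the achieved
#'   residual in attribute \code{"residual"}.
#' @export
solve_elastic_state <- function(state, pressure, lambda_z = state$lz,
                                support = NULL, tol = NULL) {
  stopifnot(inherits(state, "gr_state"))
  par <- state$par
  comp <- state$comp
  if (is.null(support)) support <- if (is.null(state$support)) 1 else state$support
  P_kPa <- mmHg_to_kPa(pressure)
  scale <- max(abs(laplace_stress(max(pressure, 120), par$a0, par$h0)), 1)
  if (is.null(tol)) tol <- 1e-9 * scale

  # overflow of the fibre exponentials at a trial stretch far beyond the
  # natural state signals stress >> demand: a large positive residual
  f <- function(lt) tryCatch(
    .elastic_residual(lt, lambda_z, comp, P_kPa, par, support),
    error = function(e) 1e12)
  # bracket around the natural-state stretch of the composition
  lo <- 0.25 * comp$lth
  hi <- 1.6 * comp$lth + 0.2
  flo <- f(lo); fhi <- f(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 6) {
    lo <- lo * 0.7; hi <- hi * 1.4
    flo <- f(lo); fhi <- f(hi); tries <- tries + 1
  }
  if (flo * fhi > 0)
    stop(sprintf("no equilibrium in bracket [%.3g, %.3g] (residuals %.3g, %.3g)",
                 lo, hi, flo, fhi))
  lt <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # Newton polish to the stated residual tolerance
  for (it in 1:8) {
    r <- f(lt)
    if (abs(r) < tol) break
    d <- 1e-7 * lt
    lt <- lt - r / ((f(lt + d) - r) / d)
  }
  out <- vessel_state(par, lt = lt, lz = lambda_z, pressure = pressure,
                      composition = comp)
  out$support <- support
  attr(out, "residual") <- f(lt)
  # the Fung form is symmetric in (I4 - 1); simulated states are expected to
  # keep fibres at or above their deposition stretch
  I4 <- .mix_mech(lt, lambda_z, comp, P_kPa, par)$I4
  if (any(I4 < 1 - 1e-6))
    warning("fibre family under compression (I4 < 1) in solved state")
  out
}

#' Evaluate the reported geometric and mechanical metrics
#'
#' Stored energy and small-on-large stiffnesses are evaluated on the
#' diastolic state; diameter and thickness are diastolic; distensibility uses
#' the diameter-based clinical form
#' \eqn{D = (d_{sys} - d_{dia}) / (d_{dia} (P_{sys} - P_{dia}))} in 1/mmHg.
#'
#' @param systolic,diastolic \code{gr_state} objects sharing one composition,
#'   at systolic and diastolic pressure respectively.
#' @param wild_type_refs optional list with element \code{inner_diameter_mm}
#'   (wild-type diastolic diameter) used for the normalized diameter; if
#'   omitted the diameter ratio is \code{NA}.
#' @return a one-row \code{data.frame} with columns \code{W_kPa},
#'   \code{c_tttt_MPa}, \code{c_zzzz_MPa}, \code{distensibility_per_mmHg},
#'   \code{inner_diameter_mm}, \code{diameter_ratio_WT}, \code{thickness_mm}.
#' @export
compute_metrics <- function(systolic, diastolic, wild_type_refs = NULL) {
  stopifnot(inherits(systolic, "gr_state"), inherits(diastolic, "gr_state"))
  if (!isTRUE(all.equal(systolic$comp, diastolic$comp)))
    stop("systolic and diastolic states must share one composition")
  ms <- .mix_mech(systolic$lt, systolic$lz, systolic$comp,
                  mmHg_to_kPa(systolic$pressure), systolic$par)
  md <- .mix_mech(diastolic$lt, diastolic$lz, diastolic$comp,
                  mmHg_to_kPa(diastolic$pressure), diastolic$par)
  cc <- small_on_large_stiffness(diastolic)
  d_sys <- 2 * ms$a
  d_dia <- 2 * md$a
  dP <- systolic$pressure - diastolic$pressure
  D <- if (dP > 0) (d_sys - d_dia) / (d_dia * dP) else 0
  ratio <- if (!is.null(wild_type_refs) &&
               !is.null(wild_type_refs$inner_diameter_mm))
    d_dia / wild_type_refs$inner_diameter_mm else NA_real_
  data.frame(W_kPa = md$W,
             c_tttt_MPa = unname(cc["c_tttt"]),
             c_zzzz_MPa = unname(cc["c_zzzz"]),
             distensibility_per_mmHg = D,
             inner_diameter_mm = d_dia,
             diameter_ratio_WT = ratio,
             thickness_mm = md$h)
}
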