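# Mechanobiologically equilibrated growth-and-remodelling solver.
#
# The hereditary constrained-mixture integrals are used in their equilibrated
# limit: at long times production balances removal, so every turned-over
# constituent (smooth muscle, collagen) carries exactly its deposition
# stretch in the evolved configuration, and the stimulus balance
#   Ksigma * dsigma - Ktauw * dtauw = omega * dsigma^2
# with dsigma = ((1 - delta) sigma - sigma_o) / sigma_o,
#      dtauw  = ((1 - xi) tauw - tauw_o) / tauw_o, tauw/tauw_o = (a0/a)^3,
# replaces the transient kinetics.  Unknowns at one cross-section: the
# evolved mixture stretch lambda_theta^h and the collagen referential mass
# ratio m^c, with the equilibrated muscle-collagen coupling m^m = (m^c)^eta.

#' Initialize the homeostatic in-vivo state
#'
#' Establishes the baseline vessel at systolic pressure and computes the
#' homeostatic targets: the intramural stress set-point (one-third trace of
#' the Cauchy stress), the unit-normalized wall shear target, and the
#' perivascular support fraction that renders the in-vivo state an exact
#' membrane equilibrium with the given material parameters (the mixture
#' stress and the thin-wall Laplace demand differ by a few percent on a
#' mid-wall ring; the support fraction carries the difference, emulating the
#' tethering the full vessel provides).
#'
#' @param par a \code{gr_params} object, see [vessel_params()].
#' @param P_sys systolic pressure (mmHg), default 120.
#' @return a list of class \code{gr_baseline} with elements \code{state}
#'   (a \code{gr_state} at \code{P_sys}) and \code{targets} (list with
#'   \code{sigma_o} (kPa), \code{tauw_o} (= 1), \code{a0}, \code{h0},
#'   \code{support}, \code{P_sys}).
#' @export
init_homeostatic <- function(par, P_sys = 120) {
  .validate_params(par)
  st <- vessel_state(par, lt = 1, lz = 1, pressure = P_sys)
  m <- .mix_mech(1, 1, st$comp, mmHg_to_kPa(P_sys), par)
  support <- m$sig[["t"]] / (mmHg_to_kPa(P_sys) * m$a / m$h)
  st$support <- support
  targets <- list(sigma_o = m$sigbar, tauw_o = 1,
                  a0 = par$a0, h0 = par$h0,
                  support = support, P_sys = P_sys)
  structure(list(state = st, targets = targets, par = par),
            class = "gr_baseline")
}

# Residuals of the equilibrated system at one insult level.
# x = (lth, mc); returns c(R1 mechanobiological, R2 mechanical), normalized.
.gnr_residual <- function(x, ins, gnr, baseline) {
  par <- baseline$par
  tg <- baseline$targets
  lth <- x[1]; mc <- x[2]
  if (lth <= 0 || mc <= 0) return(c(NA_real_, NA_real_))
  comp <- .composition(par, mc = mc, mm = mc^gnr$eta,
                       tce = ins$tce, tGc = ins$tGc,
                       lth = lth, lzh = 1,
                       alpha0h = atan(lth^gnr$gamma * tan(par$alpha0)),
                       delta = ins$tdelta)
  P_kPa <- mmHg_to_kPa(ins$pressure)
  m <- .mix_mech(lth, 1, comp, P_kPa, par)
  dsig <- ((1 - ins$tdelta) * m$sigbar - tg$sigma_o) / tg$sigma_o
  dtau <- (1 - gnr$xi) * (tg$a0 / m$a)^3 - 1
  R1 <- dsig - gnr$KtK * dtau - gnr$omega * dsig^2
  R2 <- (m$sig[["t"]] - tg$support * P_kPa * m$a / m$h) / abs(tg$sigma_o)
  c(R1, R2)
}

# Damped Newton with finite-difference Jacobian on the 2-unknown system.
.gnr_newton <- function(x, ins, gnr, baseline, tol = 1e-9, maxit = 60) {
  for (it in seq_len(maxit)) {
    R <- .gnr_residual(x, ins, gnr, baseline)
    if (any(!is.finite(R))) return(list(x = x, ok = FALSE, res = R))
    if (max(abs(R)) < tol) return(list(x = x, ok = TRUE, res = R))
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      d <- 1e-7 * max(abs(x[j]), 1)
      xp <- x; xp[j] <- xp[j] + d
      J[, j] <- (.gnr_residual(xp, ins, gnr, baseline) - R) / d
    }
    dx <- tryCatch(solve(J, -R), error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, ok = FALSE, res = R))
    lam <- 1
    while (any(x + lam * dx <= c(1e-3, 1e-4)) && lam > 1e-10) lam <- lam / 2
    x <- x + lam * dx
    if (x[1] > 12 || x[2] > 100)
      return(list(x = x, ok = FALSE, res = R)) # unbounded dilatation
  }
  list(x = x, ok = max(abs(.gnr_residual(x, ins, gnr, baseline))) < tol, res = R)
}

#' Solve the mechanobiologically equilibrated evolved state
#'
#' Applies the apex insult triple gradually over continuation increments at
#' fixed pressure and solves, at each increment, the coupled mechanical and
#' mechanobiological equilibrium for the evolved circumferential stretch and
#' the collagen mass ratio.  The equilibrated closures are: muscle-collagen
#' mass coupling \code{m^m = (m^c)^eta}; elastin mass fixed (\code{m^e = 1})
#' with its modulus reduced by the elastic-fibre insult; the collagen
#' deposition stretch reduced by the mechanoregulation insult; the sensed
#' intramural stress attenuated by the mechanosensing insult (delta); and the
#' diagonal collagen angle updated as
#' \code{tan(alpha0h) = (lambda_theta^h / lambda_z^h)^gamma * tan(alpha00)}.
#'
#' @param insults named list or vector with \code{tce}, \code{tdelta},
#'   \code{tGc}: apex insult magnitudes.
#' @param gnr a \code{gr_gnr} parameter set ([gnr_params()] /
#'   [gnr_params_apex()]).  \code{gnr$delta} is ignored; the mechanosensing
#'   attenuation is taken from \code{insults$tdelta}.
#' @param baseline a \code{gr_baseline} from [init_homeostatic()].
#' @param pressure luminal pressure held during G&R (mmHg); default the
#'   baseline systolic pressure (a different value simulates a sustained
#'   pressure step).
#' @param n_increments continuation increments (default 10).
#' @param tol normalized residual tolerance (default 1e-9).
#' @return a \code{gr_state} at \code{pressure} whose composition is the
#'   evolved equilibrated one; attributes \code{"residual"} (final residual
#'   pair) and \code{"m_c"}, \code{"m_m"} for convenience.
#' @export
solve_equilibrated <- function(insults, gnr, baseline,
                               pressure = baseline$targets$P_sys,
                               n_increments = 10, tol = 1e-9) {
  stopifnot(inherits(baseline, "gr_baseline"))
  ins_final <- list(tce = insults[["tce"]], tdelta = insults[["tdelta"]],
                    tGc = insults[["tGc"]])
  if (any(vapply(ins_final, is.null, logical(1))))
    stop("insults must provide tce, tdelta, tGc")
  if (ins_final$tce < 0 || ins_final$tce >= 1)
    stop("tce must lie in [0, 1)")
  par <- baseline$par
  x <- c(1, 1)
  dP <- pressure - baseline$targets$P_sys
  for (k in seq_len(n_increments)) {
    f <- k / n_increments
    ins <- list(tce = ins_final$tce * f, tdelta = ins_final$tdelta * f,
                tGc = ins_final$tGc * f,
                pressure = baseline$targets$P_sys + dP * f)
    sol <- .gnr_newton(x, ins, gnr, baseline, tol = tol)
    if (!sol$ok)
      stop(sprintf(paste0("equilibrated G&R solve failed at increment %d/%d ",
                          "(insult fraction %.2f): unbounded dilatation or ",
                          "non-convergence (lth=%.3g, m_c=%.3g)"),
                   k, n_increments, f, sol$x[1], sol$x[2]))
    x <- sol$x
  }
  comp <- .composition(par, mc = x[2], mm = x[2]^gnr$eta,
                       tce = ins_final$tce, tGc = ins_final$tGc,
                       lth = x[1], lzh = 1,
                       alpha0h = atan(x[1]^gnr$gamma * tan(par$alpha0)),
                       delta = ins_final$tdelta)
  st <- vessel_state(par, lt = x[1], lz = 1, pressure = pressure,
                     composition = comp)
  st$support <- baseline$targets$support
  attr(st, "residual") <- sol$res
  attr(st, "m_c") <- x[2]
  attr(st, "m_m") <- x[2]^gnr$eta
  st
}

#' Sweep evolved metrics over elastin porosity
#'
#' For each porosity: compute the apex insult triple for the scenario, solve
#' the equilibrated state at systolic pressure, unload elastically to
#' diastolic pressure, and evaluate the metric set.  The apex
#' growth-and-remodelling switch (eta = 1, Ktauw/Ksigma = 0) applies for any
#' nonzero insult; the single-insult scenarios \code{sensing_only} and
#' \code{regulation_only} ramp linearly in normalized porosity up to their
#' caps (0.150 and 0.012).
#'
#' @param porosities elastin porosity values within the experimental bounds.
#' @param A a \code{gr_insult_params} object ([insult_params()]).
#' @param scenario one of \code{"elastic_only"}, \code{"sensing_only"},
#'   \code{"regulation_only"}, \code{"combined"}.
#' @param baseline a \code{gr_baseline} from [init_homeostatic()].
#' @param P_dia diastolic evaluation pressure (mmHg), default 80.
#' @param n_increments continuation increments per porosity (default 10).
#' @return a \code{data.frame}, one row per porosity, with the insult triple,
#'   the evolved-state summary (\code{lambda_theta}, \code{m_c}, \code{m_m},
#'   \code{alpha0_deg}), the metric columns of [compute_metrics()], and a
#'   \code{converged} flag (failed porosities carry NA metrics).
#' @export
porosity_sweep <- function(porosities, A, scenario = c("combined",
                           "elastic_only", "sensing_only", "regulation_only"),
                           baseline, P_dia = 80, n_increments = 10) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(A, "gr_insult_params"), inherits(baseline, "gr_baseline"))
  if (any(porosities < A$eps_lb - 1e-9) || any(porosities > A$eps_ub + 1e-9))
    stop("porosities must lie within [eps_lb, eps_ub]")
  wt <- .baseline_metrics(baseline, P_dia = P_dia)
  rows <- lapply(porosities, function(eps) {
    ins <- .scenario_insults(eps, A, scenario)
    gnr <- if (ins$tce == 0 && ins$tdelta == 0 && ins$tGc == 0)
      gnr_params(eta = baseline$par$eta, KtK = baseline$par$KtK,
                 gamma = baseline$par$gamma)
    else gnr_params_apex(gamma = baseline$par$gamma)
    res <- tryCatch({
      sys <- solve_equilibrated(ins, gnr, baseline,
                                n_increments = n_increments)
      dia <- solve_elastic_state(sys, P_dia)
      met <- compute_metrics(sys, dia,
                             wild_type_refs = list(inner_diameter_mm =
                                                     wt$inner_diameter_mm))
      cbind(data.frame(porosity = eps, tce = ins$tce, tdelta = ins$tdelta,
                       tGc = ins$tGc, lambda_theta = sys$lt,
                       m_c = attr(sys, "m_c"), m_m = attr(sys, "m_m"),
                       alpha0_deg = sys$comp$alpha0h * 180 / pi,
                       converged = TRUE),
            met)
    }, error = function(e) {
      warning(sprintf("porosity %.4f failed: %s", eps, conditionMessage(e)),
              call. = FALSE)
      cbind(data.frame(porosity = eps, tce = ins$tce, tdelta = ins$tdelta,
                       tGc = ins$tGc, lambda_theta = NA_real_,
                       m_c = NA_real_, m_m = NA_real_, alpha0_deg = NA_real_,
                       converged = FALSE),
            data.frame(W_kPa = NA_real_, c_tttt_MPa = NA_real_,
                       c_zzzz_MPa = NA_real_,
                       distensibility_per_mmHg = NA_real_,
                       inner_diameter_mm = NA_real_,
                       diameter_ratio_WT = NA_real_, thickness_mm = NA_real_))
    })
    res
  })
  do.call(rbind, rows)
}

# Zero-insult (wild-type-like) metric set used as normalizers.
.baseline_metrics <- function(baseline, P_dia = 80) {
  sys <- baseline$state
  dia <- solve_elastic_state(sys, P_dia)
  met <- compute_metrics(sys, dia)
  met$diameter_ratio_WT <- 1
  met
}

#' Wild-type (zero-insult) metric normalizers
#'
#' Diastolic metric set of the baseline vessel, used as Y_WT normalizers in
#' the objective and by the synthetic-data generator.
#'
#' @param baseline a \code{gr_baseline}.
#' @param P_dia diastolic pressure (mmHg).
#' @return one-row \code{data.frame} of metrics (see [compute_metrics()]).
#' @export
wild_type_metrics <- function(baseline, P_dia = 80) {
  .baseline_metrics(baseline, P_dia = P_dia)
}
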