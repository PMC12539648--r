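# Constituent strain energies, mixture stress and small-on-large stiffness.
#
# Kinematic conventions: the original in-vivo systolic configuration is the
# mixture reference (F = I there).  A vessel state carries the mixture
# stretches (lt, lz) relative to that reference and a composition describing
# the frozen G&R state: referential mass ratios, insult-reduced moduli and
# deposition stretches, the mixture stretches (lth, lzh) of the equilibrated
# configuration at which turned-over constituents carry exactly their
# deposition stretch, and the evolved diagonal collagen angle.

#' Neo-Hookean strain energy of the amorphous elastin matrix
#'
#' @param I1 first invariant of the constituent elastic deformation.
#' @param ce elastin modulus (kPa).
#' @param half if \code{TRUE} (default) use (ce/2)(I1 - 3); if \code{FALSE}
#'   use ce(I1 - 3).
#' @return energy density (kPa, per unit constituent volume).
#' @export
neo_hookean_energy <- function(I1, ce, half = TRUE) {
  if (any(!is.finite(I1))) stop("I1 must be finite")
  if (any(I1 < 3 - 1e-9)) stop("I1 < 3: not an attainable isochoric state")
  fac <- if (half) 0.5 else 1
  fac * ce * (I1 - 3)
}

#' Fung exponential fibre strain energy
#'
#' Symmetric in (I4 - 1): no tension-only switch; all simulated states keep
#' fibres pre-stretched at or above their deposition stretch.
#'
#' @param I4 squared fibre stretch (> 0).
#' @param c1 fibre modulus (kPa).
#' @param c2 dimensionless exponent (> 0).
#' @return energy density (kPa).
#' @export
fung_fiber_energy <- function(I4, c1, c2) {
  if (any(!is.finite(I4)) || any(I4 <= 0)) stop("I4 must be finite and > 0")
  if (any(c2 <= 0)) stop("c2 must be > 0")
  ex <- c2 * (I4 - 1)^2
  if (any(ex > 700)) stop("fung_fiber_energy: non-physical state (exponent overflow)")
  c1 / (4 * c2) * (exp(ex) - 1)
}

# 2 * I4 * dW/dI4 for a Fung fibre: uniaxial Cauchy stress magnitude.
.fung_sigma <- function(I4, c1, c2) {
  ex <- c2 * (I4 - 1)^2
  if (any(ex > 700)) stop("fibre stress overflow: non-physical state")
  c1 * I4 * (I4 - 1) * exp(ex)
}

# 2 * dW/dI4 and 4 * d2W/dI4^2 (needed for linearized stiffness)
.fung_dW <- function(I4, c1, c2) {
  ex <- exp(c2 * (I4 - 1)^2)
  list(twoW4  = c1 * (I4 - 1) * ex,
       fourW44 = 2 * c1 * ex * (1 + 2 * c2 * (I4 - 1)^2))
}

# Composition of the frozen G&R state.
.composition <- function(par, mc = 1, mm = 1, tce = 0, tGc = 0,
                         lth = 1, lzh = 1, alpha0h = par$alpha0, delta = 0) {
  list(mc = mc, mm = mm,
       ce_eff = par$ce * (1 - tce),
       Gc_eff = par$Gc * (1 - tGc),
       lth = lth, lzh = lzh, alpha0h = alpha0h, delta = delta,
       tce = tce, tGc = tGc)
}

#' Construct a vessel state
#'
#' @param par a \code{gr_params} object, see [vessel_params()].
#' @param lt,lz mixture circumferential and axial stretch relative to the
#'   original in-vivo reference.
#' @param pressure luminal pressure (mmHg).
#' @param composition frozen G&R composition; defaults to the baseline
#'   (all referential mass ratios 1, no insult).
#' @return an object of class \code{gr_state}.
#' @export
vessel_state <- function(par, lt = 1, lz = 1, pressure = 120,
                         composition = NULL) {
  if (lt <= 0 || lz <= 0) stop("stretches must be positive")
  if (pressure < 0) stop("pressure must be >= 0")
  if (is.null(composition)) composition <- .composition(par)
  structure(list(par = par, lt = lt, lz = lz, pressure = pressure,
                 comp = composition),
            class = "gr_state")
}

# Core mixture evaluation at mixture stretches (lt, lz) and pressure P (kPa).
# Returns stresses (kPa), stored energy per unit current volume (kPa),
# geometry (mm), total referential mass ratio M and current mass fractions.
.mix_mech <- function(lt, lz, comp, P_kPa, par) {
  if (lt <= 0 || lz <= 0) stop("non-positive stretch")
  M <- par$phi_e + par$phi_m * comp$mm + par$phi_c * comp$mc
  fe <- par$phi_e / M
  fm <- par$phi_m * comp$mm / M
  fc <- par$phi_c * comp$mc / M

  # elastin: natural configuration tied to the original reference
  le_r <- par$G_r_e / (lt * lz)
  le_t <- lt * par$G_theta_e
  le_z <- lz * par$G_z_e
  I1 <- le_r^2 + le_t^2 + le_z^2
  We <- neo_hookean_energy(I1, comp$ce_eff, half = par$neo_hookean_half)
  nh_fac <- if (par$neo_hookean_half) 1 else 2 # sigma = 2 dW/dI1 * lambda^2
  sig_e <- nh_fac * comp$ce_eff * c(le_r, le_t, le_z)^2

  # smooth muscle: circumferential, natural state at the equilibrated config
  I4m <- (lt / comp$lth)^2 * par$Gm^2
  Wm <- fung_fiber_energy(I4m, par$c1m, par$c2m)
  sig_m_t <- .fung_sigma(I4m, par$c1m, par$c2m)

  # collagen families: circumferential, axial, symmetric +/- diagonal
  ang <- c(pi / 2, 0, comp$alpha0h, comp$alpha0h)
  bfr <- c(par$beta_theta, par$beta_z, par$beta_d / 2, par$beta_d / 2)
  qt <- (lt / comp$lth)^2 * sin(ang)^2
  qz <- (lz / comp$lzh)^2 * cos(ang)^2
  I4c <- comp$Gc_eff^2 * (qt + qz)
  dc <- .fung_dW(I4c, par$c1c, par$c2c)
  sig_c_t <- sum(bfr * dc$twoW4 * comp$Gc_eff^2 * qt)
  sig_c_z <- sum(bfr * dc$twoW4 * comp$Gc_eff^2 * qz)
  Wc <- sum(bfr * fung_fiber_energy(I4c, par$c1c, par$c2c))

  # radial reaction: mid-wall mean sigma_rr = -P/2
  preac <- fe * sig_e[1] + P_kPa / 2
  sig_t <- fe * sig_e[2] + fm * sig_m_t + fc * sig_c_t - preac
  sig_z <- fe * sig_e[3] + fc * sig_c_z - preac
  sig_r <- -P_kPa / 2

  # geometry: mid-wall stretch + exact annular area conservation
  rmid0 <- par$a0 + par$h0 / 2
  h <- par$h0 * M / (lt * lz)
  rmid <- lt * rmid0
  a <- rmid - h / 2

  list(sig = c(r = sig_r, t = sig_t, z = sig_z),
       W = fe * We + fm * Wm + fc * Wc,
       a = a, h = h, M = M, fe = fe, fm = fm, fc = fc,
       sigbar = (sig_t + sig_z + sig_r) / 3,
       I4 = c(m = I4m, c_min = min(I4c)))
}

# Analytic linearized (small-on-large) stiffness about (lt, lz):
# c_tttt = d sigma_tt / d ln(lt) at fixed lz, P, frozen composition,
# including the radial-reaction variation; c_zzzz analogous.
.mix_stiffness <- function(lt, lz, comp, P_kPa, par) {
  M <- par$phi_e + par$phi_m * comp$mm + par$phi_c * comp$mc
  fe <- par$phi_e / M
  fm <- par$phi_m * comp$mm / M
  fc <- par$phi_c * comp$mc / M
  nh_fac <- if (par$neo_hookean_half) 1 else 2

  le_r2 <- (par$G_r_e / (lt * lz))^2
  ct_e <- 2 * nh_fac * comp$ce_eff * (lt * par$G_theta_e)^2
  cz_e <- 2 * nh_fac * comp$ce_eff * (lz * par$G_z_e)^2
  # reaction pressure p = fe*sig_e_r + P/2;  d p/d ln(lt) = -2 fe sig_e_r
  dp <- 2 * fe * nh_fac * comp$ce_eff * le_r2 # enters with + sign in c

  I4m <- (lt / comp$lth)^2 * par$Gm^2
  dm <- .fung_dW(I4m, par$c1m, par$c2m)
  ct_m <- dm$fourW44 * I4m^2 + 2 * dm$twoW4 * I4m

  ang <- c(pi / 2, 0, comp$alpha0h, comp$alpha0h)
  bfr <- c(par$beta_theta, par$beta_z, par$beta_d / 2, par$beta_d / 2)
  qt <- comp$Gc_eff^2 * (lt / comp$lth)^2 * sin(ang)^2
  qz <- comp$Gc_eff^2 * (lz / comp$lzh)^2 * cos(ang)^2
  I4c <- qt + qz
  dc <- .fung_dW(I4c, par$c1c, par$c2c)
  ct_c <- sum(bfr * (dc$fourW44 * qt^2 + 2 * dc$twoW4 * qt))
  cz_c <- sum(bfr * (dc$fourW44 * qz^2 + 2 * dc$twoW4 * qz))

  c(c_tttt = fe * ct_e + fm * ct_m + fc * ct_c + dp,
    c_zzzz = fe * cz_e + fc * cz_c + dp)
}

#' Mixture stored energy of a vessel state
#'
#' Rule-of-mixtures stored energy: current mass fractions weight the
#' constituent energy densities, with collagen split over the four fibre
#' families by their orientation fractions.
#'
#' @param state a \code{gr_state}, see [vessel_state()].
#' @return stored energy (kPa, per unit current volume).
#' @export
mixture_stored_energy <- function(state) {
  stopifnot(inherits(state, "gr_state"))
  .mix_mech(state$lt, state$lz, state$comp,
            mmHg_to_kPa(state$pressure), state$par)$W
}

#' Mixture Cauchy stress of a vessel state
#'
#' Membrane (mid-wall) evaluation: deviatoric contributions from the
#' constituent energies (elastin as a full three-dimensional neo-Hookean
#' push-forward, fibres uniaxial along their current orientation), with the
#' incompressibility reaction fixed by the mid-wall radial traction
#' condition sigma_rr = -P/2.
#'
#' @param state a \code{gr_state}.
#' @param pressure luminal pressure (mmHg); defaults to the state's pressure.
#' @return named stress triple \code{c(sig_tt, sig_zz, sig_rr)} (kPa).
#' @export
mixture_cauchy_stress <- function(state, pressure = state$pressure) {
  stopifnot(inherits(state, "gr_state"))
  m <- .mix_mech(state$lt, state$lz, state$comp,
                 mmHg_to_kPa(pressure), state$par)
  c(sig_tt = unname(m$sig["t"]), sig_zz = unname(m$sig["z"]),
    sig_rr = unname(m$sig["r"]))
}

#' Small-on-large material stiffness of a loaded vessel state
#'
#' Circumferential and axial components of the linearized material stiffness
#' about the current loaded configuration: the derivative of the Cauchy
#' stress with respect to an incremental logarithmic stretch at fixed
#' orthogonal stretch, pressure and composition, assembled analytically from
#' constituent-wise second derivatives of the stored energies pushed forward
#' to the current configuration and mass-fraction weighted.
#'
#' @param state a \code{gr_state}.
#' @param pressure luminal pressure (mmHg); defaults to the state's pressure.
#' @return named vector \code{c(c_tttt, c_zzzz)} in MPa.
#' @export
small_on_large_stiffness <- function(state, pressure = state$pressure) {
  stopifnot(inherits(state, "gr_state"))
  if (state$lt <= 0 || state$lz <= 0) stop("degenerate state")
  cc <- .mix_stiffness(state$lt, state$lz, state$comp,
                       mmHg_to_kPa(pressure), state$par)
  cc / 1000
}
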