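# Parameter handling: baseline material / G&R parameters and unit constants.

# 1 mmHg in kPa; pressures are accepted in mmHg at interfaces and converted here.
.kPa_per_mmHg <- 0.133322

#' Convert a pressure from mmHg to kPa
#'
#' @param p_mmHg pressure in mmHg.
#' @return pressure in kPa (1 mmHg = 0.133322 kPa).
#' @export
mmHg_to_kPa <- function(p_mmHg) p_mmHg * .kPa_per_mmHg

#' Baseline vessel and mixture parameters
#'
#' Constructs the full parameter set describing the non-dilated Marfan-like
#' murine ascending aorta: geometry, constituent mass fractions, collagen
#' family orientation fractions, material moduli of the neo-Hookean elastin
#' matrix and the Fung-exponential smooth muscle and collagen fibres,
#' deposition (pre-)stretches, the diagonal collagen angle, mechanosensing
#' offsets and the growth-and-remodelling gain/turnover ratios.  Defaults are
#' the packaged baseline configuration (see
#' \code{system.file("extdata", "table1_baseline.yaml", package = "aortagnr")}).
#'
#' @param ... named overrides of any configuration key, e.g. \code{ce_kPa = 40}.
#' @return an object of class \code{gr_params}: a named list with elements
#'   \code{a0} and \code{h0} (mm), mass fractions \code{phi_e}, \code{phi_m},
#'   \code{phi_c}, orientation fractions \code{beta_theta}, \code{beta_z},
#'   \code{beta_d}, moduli \code{c1m}, \code{c2m}, \code{c1c}, \code{c2c},
#'   \code{ce} (kPa where dimensional), deposition stretches \code{G_theta_e},
#'   \code{G_z_e}, \code{G_r_e} (derived as 1/(G_theta_e*G_z_e)), \code{Gm},
#'   \code{Gc}, angle \code{alpha0} (radians), \code{gamma}, \code{delta},
#'   \code{xi}, \code{eta}, \code{KtK} (shear-to-intramural gain ratio) and
#'   the logical \code{neo_hookean_half}.
#' @export
vessel_params <- function(...) {
  path <- system.file("extdata", "table1_baseline.yaml", package = "aortagnr")
  p <- read_vessel_params(path)
  ov <- list(...)
  if (length(ov)) {
    raw <- .params_to_config(p)
    bad <- setdiff(names(ov), names(raw))
    if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
    raw[names(ov)] <- ov
    p <- .config_to_params(raw)
  }
  p
}

#' Read a baseline parameter configuration file
#'
#' @param path path to a YAML file with keys \code{a0_mm, h0_mm, phi_e, phi_m,
#'   phi_c, beta_theta, beta_z, beta_d, c1m_kPa, c2m, c1c_kPa, c2c, ce_kPa,
#'   G_theta_e, G_z_e, Gm, Gc, alpha0_deg, delta, xi, eta, Ktauw_over_Ksigma}
#'   and optionally \code{gamma} and \code{neo_hookean_half}.
#' @return a \code{gr_params} object (see [vessel_params()]).
#' @export
read_vessel_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  .config_to_params(yaml::read_yaml(path))
}

.config_to_params <- function(cfg) {
  need <- c("a0_mm", "h0_mm", "phi_e", "phi_m", "phi_c",
            "beta_theta", "beta_z", "beta_d",
            "c1m_kPa", "c2m", "c1c_kPa", "c2c", "ce_kPa",
            "G_theta_e", "G_z_e", "Gm", "Gc", "alpha0_deg",
            "delta", "xi", "eta", "Ktauw_over_Ksigma")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing parameter key(s): ", paste(miss, collapse = ", "))
  # printed mass fractions may carry rounding (e.g. summing to 1.01);
  # renormalize so the fractions partition unity exactly
  phisum <- cfg$phi_e + cfg$phi_m + cfg$phi_c
  if (abs(phisum - 1) > 0.02)
    stop("mass fractions must sum to 1 (got ", signif(phisum, 4), ")")
  p <- list(
    a0 = cfg$a0_mm, h0 = cfg$h0_mm,
    phi_e = cfg$phi_e / phisum, phi_m = cfg$phi_m / phisum,
    phi_c = cfg$phi_c / phisum,
    beta_theta = cfg$beta_theta, beta_z = cfg$beta_z, beta_d = cfg$beta_d,
    c1m = cfg$c1m_kPa, c2m = cfg$c2m, c1c = cfg$c1c_kPa, c2c = cfg$c2c,
    ce = cfg$ce_kPa,
    G_theta_e = cfg$G_theta_e, G_z_e = cfg$G_z_e,
    G_r_e = 1 / (cfg$G_theta_e * cfg$G_z_e),
    Gm = cfg$Gm, Gc = cfg$Gc,
    alpha0 = cfg$alpha0_deg * pi / 180,
    gamma = if (is.null(cfg$gamma)) 0.2 else cfg$gamma,
    delta = cfg$delta, xi = cfg$xi,
    eta = cfg$eta, KtK = cfg$Ktauw_over_Ksigma,
    neo_hookean_half = if (is.null(cfg$neo_hookean_half)) TRUE else isTRUE(cfg$neo_hookean_half)
  )
  .validate_params(p)
  class(p) <- "gr_params"
  p
}

.params_to_config <- function(p) {
  list(a0_mm = p$a0, h0_mm = p$h0, phi_e = p$phi_e, phi_m = p$phi_m,
       phi_c = p$phi_c, beta_theta = p$beta_theta, beta_z = p$beta_z,
       beta_d = p$beta_d, c1m_kPa = p$c1m, c2m = p$c2m, c1c_kPa = p$c1c,
       c2c = p$c2c, ce_kPa = p$ce, G_theta_e = p$G_theta_e, G_z_e = p$G_z_e,
       Gm = p$Gm, Gc = p$Gc, alpha0_deg = p$alpha0 * 180 / pi,
       gamma = p$gamma, delta = p$delta, xi = p$xi, eta = p$eta,
       Ktauw_over_Ksigma = p$KtK, neo_hookean_half = p$neo_hookean_half)
}

.validate_params <- function(p) {
  stopifnot(p$a0 > 0, p$h0 > 0)
  if (abs(p$phi_e + p$phi_m + p$phi_c - 1) > 1e-8)
    stop("mass fractions must sum to 1")
  if (abs(p$beta_theta + p$beta_z + p$beta_d - 1) > 1e-8)
    stop("collagen orientation fractions must sum to 1")
  if (p$c2m <= 0 || p$c2c <= 0) stop("Fung exponents c2 must be > 0")
  if (p$Gm <= 1 || p$Gc <= 1) stop("scalar deposition stretches must exceed 1")
  if (p$alpha0 < 0 || p$alpha0 > pi / 2)
    stop("diagonal collagen angle must lie in [0, 90] degrees")
  if (p$delta < 0 || p$delta >= 1 || p$xi < 0 || p$xi >= 1)
    stop("mechanosensing parameters delta, xi must lie in [0, 1)")
  if (p$eta <= 0) stop("turnover ratio eta must be > 0")
  if (p$KtK < 0) stop("gain ratio Ktauw/Ksigma must be >= 0")
  invisible(TRUE)
}

#' Growth-and-remodelling parameter set
#'
#' Gain and turnover ratios entering the mechanobiological equilibrium
#' condition.  At the insult apex the vessel loses shear sensitivity
#' (\code{KtK = 0}) and smooth-muscle turnover matches collagen turnover
#' (\code{eta = 1}); away from any insult the baseline values (0.9, 0.9)
#' apply.
#'
#' @param eta smooth-muscle-to-collagen turnover ratio (> 0).
#' @param KtK ratio of wall-shear to intramural-stress gains (>= 0).
#' @param gamma collagen fibre-reorientation exponent (>= 0).
#' @param delta,xi mechanosensing attenuation parameters in [0, 1).
#' @param omega removal-stimulus weight; at equilibrium a nonzero value adds
#'   \code{omega * dsigma^2} to the stimulus balance.  Default 0.
#' @return an object of class \code{gr_gnr} (named list).
#' @export
gnr_params <- function(eta = 0.9, KtK = 0.9, gamma = 0.2,
                       delta = 0, xi = 0, omega = 0) {
  if (eta <= 0) stop("eta must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (KtK < 0) stop("KtK must be >= 0")
  if (delta < 0 || delta >= 1 || xi < 0 || xi >= 1)
    stop("delta and xi must lie in [0, 1)")
  structure(list(eta = eta, KtK = KtK, gamma = gamma,
                 delta = delta, xi = xi, omega = omega),
            class = "gr_gnr")
}

#' Apex growth-and-remodelling parameters
#'
#' Convenience constructor for the insult-apex parameter switch: loss of
#' shear sensitivity (\code{KtK = 0}) and equal smooth-muscle/collagen
#' fractional turnover (\code{eta = 1}).
#'
#' @inheritParams gnr_params
#' @return a \code{gr_gnr} object.
#' @export
gnr_params_apex <- function(delta = 0, gamma = 0.2, omega = 0) {
  gnr_params(eta = 1, KtK = 0, gamma = gamma, delta = delta, omega = omega)
}
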