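# Porosity-to-insult maps and the axial insult profile.

#' Insult parameter vector with bounds
#'
#' The optimization vector A = (theta_delta_max, theta_Gc_max, g) together
#' with the fixed elastic-fibre ceiling and the experimental porosity range.
#' The ceiling derives from the fold change in non-void elastic fibre space:
#' (eps_ub - eps_lb) / (1 - eps_lb) = 0.660.
#'
#' @param theta_delta_max maximal mechanosensing insult, in [0, 0.1].
#' @param theta_Gc_max maximal mechanoregulation insult (fractional reduction
#'   of the collagen deposition stretch), in [0, 0.015].
#' @param g insult progression-rate constant, in [0.01, 10].
#' @param theta_ce_max fixed elastic-fibre integrity ceiling (default 0.660).
#' @param eps_lb,eps_ub elastin porosity bounds (defaults 0.115, 0.699).
#' @return an object of class \code{gr_insult_params}.
#' @export
insult_params <- function(theta_delta_max = 0, theta_Gc_max = 0, g = 1,
                          theta_ce_max = 0.660,
                          eps_lb = 0.115, eps_ub = 0.699) {
  if (theta_delta_max < 0 || theta_delta_max > 0.1)
    stop("theta_delta_max out of bounds [0, 0.1]")
  if (theta_Gc_max < 0 || theta_Gc_max > 0.015)
    stop("theta_Gc_max out of bounds [0, 0.015]")
  if (g < 0.01 || g > 10) stop("g out of bounds [0.01, 10]")
  if (theta_ce_max <= 0 || theta_ce_max >= 1)
    stop("theta_ce_max must lie in (0, 1)")
  structure(list(theta_delta_max = theta_delta_max,
                 theta_Gc_max = theta_Gc_max, g = g,
                 theta_ce_max = theta_ce_max,
                 eps_lb = eps_lb, eps_ub = eps_ub),
            class = "gr_insult_params")
}

#' Normalize elastin porosity to the experimental range
#'
#' @param eps elastin porosity (void fraction), finite.
#' @param eps_lb,eps_ub lower and upper porosity bounds.
#' @return (eps - eps_lb) / (eps_ub - eps_lb), clamped to [0, 1]; the insult
#'   maps are defined on the normalized range only.
#' @export
normalize_porosity <- function(eps, eps_lb = 0.115, eps_ub = 0.699) {
  if (any(!is.finite(eps))) stop("porosity must be finite")
  pmin(pmax((eps - eps_lb) / (eps_ub - eps_lb), 0), 1)
}

#' Elastic-fibre integrity insult
#'
#' Linear in normalized porosity: theta_ce = eps_bar * theta_ce_max.
#'
#' @param eps_bar normalized porosity in [0, 1].
#' @param theta_ce_max ceiling (default 0.660).
#' @return fractional reduction of the elastin modulus.
#' @export
elastic_fibre_insult <- function(eps_bar, theta_ce_max = 0.660) {
  stopifnot(all(eps_bar >= 0), all(eps_bar <= 1))
  eps_bar * theta_ce_max
}

#' Cell-mediated insult progression
#'
#' Saturating-exponential map used for both the mechanosensing (delta) and
#' mechanoregulation (Gc) insults:
#' theta = theta_max * (exp(-g * eps_bar) - 1) / (exp(-g) - 1).
#' Zero at eps_bar = 0, theta_max at 1, strictly increasing and concave for
#' g > 0 (front-loaded progression), tending to linear as g -> 0+.
#'
#' @param eps_bar normalized porosity in [0, 1].
#' @param g progression-rate constant (> 0).
#' @param theta_max maximal insult.
#' @return insult magnitude.
#' @export
cell_insult <- function(eps_bar, g, theta_max) {
  if (g <= 0) stop("g must be > 0")
  stopifnot(all(eps_bar >= 0), all(eps_bar <= 1))
  theta_max * (exp(-g * eps_bar) - 1) / (exp(-g) - 1)
}

#' Axial profile parameters of the insult region
#'
#' @param lo model length (mm), default 15.0.
#' @param zod axial width of the insult region (mm), default 3.0.
#' @param vz boundary-softness exponent (>= 1), default 2.
#' @return an object of class \code{gr_axial_profile}.
#' @export
axial_profile_params <- function(lo = 15.0, zod = 3.0, vz = 2) {
  if (zod <= 0) stop("zod must be > 0")
  if (vz < 1) stop("vz must be >= 1")
  if (lo <= 2 * zod) stop("lo must exceed 2 * zod")
  structure(list(lo = lo, zod = zod, vz = vz), class = "gr_axial_profile")
}

#' Axial variation of an insult about the apex
#'
#' theta(z) = theta_apex * exp(-|(z - lo/2)/zod|^vz): maximal at the apex
#' (z = lo/2), symmetric, decaying to near-baseline at the fixed ends.
#' The three insults and the apex eta / gain-ratio adjustments share this
#' profile shape.
#'
#' @param zo axial coordinate(s) in [0, lo] (mm).
#' @param theta_apex insult magnitude at the apex.
#' @param profile a \code{gr_axial_profile}, see [axial_profile_params()].
#' @return insult magnitude at \code{zo}.
#' @export
axial_profile <- function(zo, theta_apex, profile = axial_profile_params()) {
  if (any(zo < 0) || any(zo > profile$lo))
    stop("zo must lie in [0, lo]")
  theta_apex * exp(-abs((zo - profile$lo / 2) / profile$zod)^profile$vz)
}

# Insult triple at the apex for a given porosity and scenario.
.scenario_insults <- function(eps, A, scenario,
                              sensing_cap = 0.150, regulation_cap = 0.012) {
  eb <- normalize_porosity(eps, A$eps_lb, A$eps_ub)
  switch(scenario,
    elastic_only = list(tce = elastic_fibre_insult(eb, A$theta_ce_max),
                        tdelta = 0, tGc = 0),
    sensing_only = list(tce = 0, tdelta = eb * sensing_cap, tGc = 0),
    regulation_only = list(tce = 0, tdelta = 0, tGc = eb * regulation_cap),
    combined = list(tce = elastic_fibre_insult(eb, A$theta_ce_max),
                    tdelta = cell_insult(eb, A$g, A$theta_delta_max),
                    tGc = cell_insult(eb, A$g, A$theta_Gc_max)),
    stop("unknown scenario: ", scenario))
}
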