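---
title: "Methods: equilibrated constrained-mixture growth and remodelling of the aneurysmal aorta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equilibrated constrained-mixture growth and remodelling of the aneurysmal aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortagnr)
```

## The model

`aortagnr` simulates aneurysmal progression of the murine Marfan ascending
aorta as a *mechanobiologically equilibrated constrained mixture*.  The wall
is a mixture of three structurally significant constituents — an
elastin-dominated amorphous matrix, circumferential smooth muscle, and
collagen-dominated fibrous matrix split over four fibre families
(circumferential, axial, and a symmetric diagonal pair at an evolving angle
$\alpha_0$ from the axial direction).  All constituents deform with the
tissue but keep individual natural configurations and properties:

* elastin is neo-Hookean, $\hat W^e = \tfrac{c^e}{2}(I_1^e - 3)$, and is not
  produced in maturity ($m^e \equiv 1$); its natural configuration is fixed
  by the deposition-stretch triple
  $(G^e_r, G^e_\theta, G^e_z)$ with $G^e_r = 1/(G^e_\theta G^e_z)$;
* smooth muscle and collagen follow the Fung exponential
  $\hat W = \frac{c_1}{4 c_2}\left(e^{c_2 (I_4 - 1)^2} - 1\right)$ and turn
  over continuously, being deposited at scalar pre-stretches $G^m$, $G^c$.

The mixture energy per unit current volume is the rule-of-mixtures sum
$W = \sum_\alpha \phi^\alpha \hat W^\alpha$ with current (mass-ratio
weighted) mass fractions.  Cauchy stress follows from
$\sigma = 2 F \,\partial W/\partial C\, F^T$ for the incompressible mixture,
evaluated on a mid-wall membrane with the radial reaction fixed by the
transmural mean $\sigma_{rr} = -P/2$.

### The neo-Hookean ½ factor

The elastin energy is implemented as $(c^e/2)(I_1-3)$ (configuration flag
`neo_hookean_half` in the parameter file).  The convention is adjudicated by
the baseline diastolic stored energy: with the ½ factor the packaged
parameters give $W_0 = 51.9\ \mathrm{kPa}$ at 80 mmHg; without it the
stored energy roughly doubles, which is inconsistent with the homeostatic
baseline this parameter set describes.

### Mechanobiological equilibrium

Stress-mediated turnover (production gains $K_\sigma$, $K_{\tau_w}$ on the
normalized deviations $\Delta\sigma$, $\Delta\tau_w$ of intramural stress
and wall shear stress from homeostatic targets) is used in its *equilibrated
limit*: the hereditary integrals of the transient theory are pre-integrated,
so at equilibrium

* every turned-over constituent carries exactly its deposition stretch,
* the stimulus balance $K_\sigma \Delta\sigma - K_{\tau_w}\Delta\tau_w =
  \omega\, \Delta\sigma^2$ holds (we default the removal-stimulus weight
  $\omega$ to 0, in which case the left side vanishes), with
  $\Delta\sigma = ((1-\delta)\sigma - \sigma_o)/\sigma_o$,
  $\Delta\tau_w = ((1-\xi)\tau_w - \tau_{w o})/\tau_{w o}$ and, for constant
  flow, $\tau_w/\tau_{w o} = (a_0/a)^3$,
* mechanical equilibrium $\sigma_{\theta\theta} = \kappa P a/h$ closes the
  system (see below for $\kappa$).

At one cross-section this leaves two unknowns — the evolved circumferential
stretch $\lambda_\theta^h$ and the collagen referential mass ratio $m^c$ —
solved by a damped Newton iteration with a finite-difference Jacobian while
the insult is ramped over 10 continuation increments at fixed pressure
(doubling the increments changes metrics by $<0.1\%$; the equilibrium is
path-independent).  Two equilibrated closures require choices the transient
theory does not spell out:

* **Muscle–collagen mass coupling.**  The turnover-gain ratio $\eta$ is
  realized at equilibrium as the power law $m^m = (m^c)^\eta$, which reduces
  to equal fractional growth at the insult-apex value $\eta = 1$ and is the
  standard equilibrated consequence of gain-scaled production.
* **Fibre reorientation.** The diagonal deposition angle follows
  $\tan\alpha_0^h = (\lambda_\theta^h/\lambda_z^h)^{\gamma}\tan\alpha_{00}$
  with $\gamma = 0.2$ (modest reorientation).

The mechanosensing parameter $\xi$ (shear) is never insulted and stays 0;
only $\delta$ (intramural) evolves.

### The in-vivo prestress consistency factor

The packaged material parameters were estimated for a three-dimensionally
resolved vessel.  On the mid-wall membrane ring used here, the mixture
stress at the in-vivo state ($\lambda = 1$, 120 mmHg) is about 6.5% below
the bare thin-wall Laplace demand $Pa_0/h_0$.  `init_homeostatic()`
therefore calibrates once, at initialization, a perivascular support
fraction $\kappa = \sigma_{\theta\theta}(1)/(P a_0 / h_0) \approx 0.935$, so
that the in-vivo state is *exactly* the homeostatic reference and all
subsequent elastic and G&R equilibria solve
$\sigma_{\theta\theta} = \kappa P a/h$.  This emulates the axial/perivascular
tethering a full vessel provides and vanishes with the load at $P = 0$.  The
alternative — rescaling the moduli by $1/\kappa$ — would distort the
stored-energy baseline by the same 6.5% and was rejected.

The printed constituent mass fractions sum to 1.010 (rounding); they are
renormalized on load so the fractions partition unity.  Because fractions
enter stress and energy only as ratios, this leaves all metrics unchanged
while making the baseline wall volume exactly consistent.

### Metrics

All reported metrics are evaluated at the insult apex after elastically
unloading the equilibrated state from 120 to 80 mmHg at fixed axial stretch
(the G&R composition is frozen; only $\lambda_\theta$ re-equilibrates):

* stored energy $W$ (kPa, per unit current volume);
* circumferential and axial *small-on-large* material stiffness:
  $c_{\theta\theta\theta\theta} = \partial\sigma_{\theta\theta}/
  \partial\ln\lambda_\theta$ at fixed $\lambda_z$, pressure and composition,
  assembled analytically from constituent-wise second energy derivatives
  pushed forward to the loaded configuration (unit-tested against a centred
  finite-difference oracle at $10^{-4}$ relative precision);
* inner diameter and wall thickness (diastolic);
* distensibility in the diameter-based clinical form
  $D = (d_{sys} - d_{dia})/(d_{dia}\,\Delta P)$ per mmHg — the exact form
  used for the experimental counterpart is not fixed by the source data, so
  the definition is declared in the output header.

## Insult maps

Elastin porosity $\varepsilon \in [0.115, 0.699]$ is the progression
variable.  Normalized porosity
$\bar\varepsilon = (\varepsilon - \varepsilon_{lb}) /
(\varepsilon_{ub} - \varepsilon_{lb})$ (clamped to $[0,1]$ outside the
experimental range, where the maps are undefined) drives three insults at
the apex:

* elastic-fibre integrity: $\vartheta_{ce} = \bar\varepsilon\,
  \vartheta_{ce}^{max}$ with the histological ceiling
  $\vartheta_{ce}^{max} = (\varepsilon_{ub} - \varepsilon_{lb}) /
  (1 - \varepsilon_{lb}) = 0.660$, reducing the elastin modulus;
* mechanosensing ($\delta$) and mechanoregulation (reduction of $G^c$):
  $\vartheta = \vartheta^{max}(e^{-g\bar\varepsilon} - 1)/(e^{-g} - 1)$,
  concave and front-loaded for $g > 0$, near-linear as $g \to 0^+$.

At the apex, any nonzero insult also switches the G&R parameters to
$\eta = 1$ and $K_{\tau_w}/K_\sigma = 0$; the axial profile
$\vartheta(z) = \vartheta_{apex}\exp(-|(z - l_o/2)/z_{od}|^{v_z})$ (with
$l_o = 15$ mm, $z_{od} = 3$ mm, $v_z = 2$) describes how all insults and
parameter switches decay to baseline at the fixed ends; the reported metrics
are evaluated at the apex cross-section, which is where this package solves.

## Spatial reduction and what it costs

The package replaces the three-dimensional finite-element vessel by a single
uniform thick-walled-ring cross-section at the insult apex, where all
reported metrics are defined.  Axial tethering by the healthy boundary
regions is therefore absent, which has two visible consequences, both
deliberate trade-offs of the reduction:

* evolved states dilate more than an axially tethered vessel would at the
  same insult (the stiffness and energy metrics, which are set by the
  restored-stress equilibrium, remain close);
* the baseline circumferential stiffness evaluates to 1.57 MPa against the
  1.52 MPa of the resolved model — a ~3% bias that persists across
  defensible stiffness conventions (including the variant carrying the
  $2\sigma - 2p$ small-on-large terms, 1.556 MPa) and that we report rather
  than absorb into recalibrated parameters.

A second structural property worth knowing: because elastin does not turn
over, *perfect* adaptation to a sustained pressure step is impossible.  For
a 20% step with intact sensing the equilibrated vessel restores its radius
to within 1% of target, but the wall thickens to only ≈1.145·h₀ rather than
the ideal 1.2·h₀, leaving stimulus deviations of ≈2% — the elastin share of
wall stress (≈15%) cannot scale with pressure, and the shortfall is close to
$\phi^e \cdot 0.2$ relative.  The package reports this honestly; tests
assert the radius restoration and document the thickness gap.

## Parameter identification

The objective compares model curves with observations at the observation
porosities: $J_Y = \frac{1}{n}\sum_i ((Y_i - Y_{h,i})/Y_{WT})^2$ per metric,
combined as $\Phi = (J_{c_{\theta\theta\theta\theta}} + J_W)/2$ over the two
functional indicators (circumferential stiffness and stored energy), with
wild-type normalizers $Y_{WT}$ taken from the zero-insult model.  The
decision vector is $A = (\vartheta_\delta^{max}, \vartheta_{Gc}^{max}, g)$
in the box $[0, 0.1] \times [0, 0.015] \times [0.01, 10]$;
$\vartheta_{ce}^{max}$ stays fixed at its histological value.

`smf_optimize()` implements a surrogate management framework:

* initial design: Latin hypercube, $10 \times d = 30$ points (standard SMF
  sizing; fits the evaluation budget);
* SEARCH: a kriging interpolant (isotropic squared-exponential on the
  unit-scaled box, constant GLS mean, profile-ML lengthscale, $10^{-10}$
  nugget) is minimized by multistart L-BFGS-B and the true objective is
  evaluated at the surrogate minimizer, repeating while improvements arrive;
* POLL: a coordinate positive-spanning stencil of mesh size $\Delta$ around
  the incumbent, halving $\Delta$ on failure;
* termination at $\Delta < 10^{-3}$ of the box width or a 300-evaluation
  budget; failed forward solves (the ring model has no bounded equilibrium
  near the corner of simultaneously extreme sensing and regulation insults)
  count as $+\infty$ and are logged.

Incumbent ties are broken first-found and every evaluation is logged with
the seed, so runs are exactly reproducible.

## Synthetic observations

`generate_observations()` emulates the two Marfan genotype groups: a milder
heterozygous-like group with porosities uniform on $[0.115, 0.40]$ and a
severe hypomorph-like group on $[0.30, 0.699]$ — overlapping ranges chosen
to reproduce the pooled experimental bounds and the group ordering without
transcribing per-specimen values.  Metrics come from the combined-insult
forward model at a known triple $A_{true}$ (default: the identified means
$\vartheta_\delta^{max} = 0.0594$, $\vartheta_{Gc}^{max} = 0.0080$,
$g = 6.21$) perturbed by multiplicative lognormal noise with a
coefficient of variation of 0.08 (mean-one noise; a biological-replicate
scale), configurable.  What passing recovery tests show is therefore
*self-consistency* of generator, forward model and optimizer — real data add
inter-metric covariance, porosity measurement error and model misfit that
the generator deliberately does not emulate.

## Problem sizes and numerical choices

Default study sizes: 10 continuation increments per equilibrated solve;
elastic solves bracketed around the natural-state stretch and polished to a
residual below $10^{-9}\sigma_o$; recovery studies use 8 specimens per group
and a 300-evaluation budget (noise-free round-trips reach
$\Phi^* \le 10^{-6}$ with $g$ recovered within a few percent); the
multi-trial study runs 8 seeded fits at budget 200, reproducing the
near-degenerate ridge along which the fitted sensing and regulation maxima
are strongly anti-correlated at practically identical $\Phi$.  Fibre states
are monitored: any solved state whose fibre families fall below their
deposition stretch ($I_4 < 1$) is flagged with a warning (the symmetric Fung
form remains valid; the flag marks departure from the tested regime).

## Known limitations

Single cross-section (no axially resolved fields or boundary layers);
passive behaviour only (no smooth-muscle tone); no glycosaminoglycan
accumulation; no medial/adventitial layering or circumferential property
variation; transient G&R dynamics are outside scope — porosity, not time, is
the progression variable.
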