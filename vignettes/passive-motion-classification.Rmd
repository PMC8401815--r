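---
title: "Passive-motion classification of microscopic particles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive-motion classification of microscopic particles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passivemotion)
```

## The problem

A microscope pointed at an environmental water sample — on Earth or on an
ocean world such as Europa or Enceladus — sees micron-scale objects that may
be non-motile cells, cell-like vesicles, or mineral grains. At 0.2–2 µm these
are barely resolved, so morphology cannot separate them, and non-motile
organisms give no behavioural signal. Their *passive* motion, however, is
informative: aquatic cells have densities close to water (almost always below
1.3 g/cm³, cytoplasm being mostly water), whereas nearly no mineral is
lighter than about 1.5 g/cm³, and nothing mineral floats. A particle's
three-dimensional trajectory therefore encodes both its size (through
lateral Brownian motion) and its density (through axial drift), and density
alone separates the two hypotheses across a persistent gap.

`passivemotion` implements this inference chain end to end: a ground-truthed
trajectory simulator emulating digital holographic microscope (DHM)
recordings, projection-based detection and linking, per-track estimators,
the density-gap classifier, and observation-time planning for arbitrary
gravity and temperature environments.

## The model

Everything rests on four closed-form results for a sphere of hydrodynamic
radius $r$ and density $\rho_p$ in a fluid of temperature $T$, dynamic
viscosity $\eta$ and density $\rho_f$ under gravity $g$:

* **Einstein–Stokes diffusivity** $D = k_B T / (6\pi\eta r)$. In water at
  20 °C this evaluates to $D \approx 0.214/r$ µm²/s for $r$ in µm, so a
  1 µm-diameter sphere diffuses at ≈ 0.43 µm²/s.
* **Brownian timescale** to cover an RMS distance $x$:
  $\tau_B = x^2/(2D)$ in one dimension, $x^2/(4D)$ in two.
* **Stokes' law** for the terminal settling velocity
  $v = 2(\rho_p - \rho_f) g r^2 / (9\eta)$, positive downward (sinking);
  the time to traverse a distance $d$ is $\tau_g = d/|v|$.
* **Particle Strouhal number**, the ratio of the gravitational transit
  timescale to the Brownian timescale over one particle radius:
  $$\mathrm{Sr}_p \;=\; \frac{\tau_g}{\tau_B} \;=\;
    \frac{3 k_B T}{4\pi\,|\rho_p-\rho_f|\,g\,r^4}.$$
  $\mathrm{Sr}_p \gg 1$ means diffusion dominates (densities must be
  recovered from long observations or ensembles); $\mathrm{Sr}_p \ll 1$
  means the particle visibly sinks or floats; the two compete near
  $\mathrm{Sr}_p \sim 1$. Note the strong $r^{-4}$ dependence — estimates
  must be made per particle, since even a modest size spread fans
  $\mathrm{Sr}_p$ across orders of magnitude — and that $\mathrm{Sr}_p$ is
  independent of viscosity and linear in $T$.

On the constant in $\mathrm{Sr}_p$: direct substitution of the 1-D
$\tau_B$ and of $\tau_g$ with $d = x_{\mathrm{RMS}} = r$ gives
$3k_BT/(2\pi\Delta\rho g r^4)$, twice the constant above. The package
implements the $3/(4\pi)$ form (locked by a regression test), which is the
convention its regime thresholds were calibrated against; since the number
is used through order-of-magnitude thresholds, the factor of two does not
move any classification in practice.

Assumptions inherited from these formulas: rigid spheres (no shape or
surface corrections), dilute suspension (no hydrodynamic coupling, no
hindered settling), quiescent fluid apart from a uniform drift, and the
overdamped limit (inertia is negligible at these Reynolds numbers).

Water properties come from standard correlations: the IAPWS (2008)
viscosity formulation evaluated on the liquid branch at atmospheric
pressure (dilute-gas times finite-density term; the critical enhancement is
irrelevant here), with Kell's (1975) 1-atm density polynomial supplying
$\rho_f(T)$. This reproduces 1.0016 mPa·s at 20 °C and 0.31417 mPa·s at
90 °C to better than 0.01%. The more-than-threefold viscosity drop between
20 and 90 °C is itself an instrument knob: heating the chamber speeds up
settling without touching $\mathrm{Sr}_p$.

## The synthetic-data generator

`simulate_population()` emulates the geometry and statistics of DHM
recordings: 15 frames/s, a 356 µm × 365 µm lateral field, a 1 mm deep
chamber, and 20–80 s recordings. Each frame advances each particle by an
exact Gaussian increment $\sqrt{2D\,\Delta t}\,\xi$ per axis (Brownian
motion is exactly discretizable, so there is no time-step bias), plus the
uniform lateral drift and the Stokes velocity along z. The chamber walls
reflect. Localization error is added afterwards as independent Gaussian
noise; the defaults $\sigma_{xy} = 0.2$ µm and $\sigma_z = 1.0$ µm are set
to a quarter–half of the 0.8 µm lateral and 2 µm axial optical resolutions,
a typical centroiding precision. All randomness flows through one master
seed with per-stage derived streams, so every artifact is bit-reproducible
from (configuration, seed).

Population structure follows the measured size distributions of the test
materials: fixed or lognormal radii for beads and cocci (polystyrene and
non-motile *Staphylococcus epidermidis* are both strongly peaked at 1.0 µm
diameter), and a cluster model for gas vesicles — streptavidin-linked
aggregates of ~0.8 µm effective monomers, whose diameter histogram shows
peaks at 0.8 µm increments. Material densities come from the packaged
reference table (`material_library()`); the diatom range 1100–1200 kg/m³ is
stored as its midpoint.

Axial starting positions: by default (`init = "transit"`) a sinking or
floating particle starts where its deterministic drift path fits inside the
chamber over the recording. This emulates an observational selection, not a
physical one — a grain that can be tracked sinking for 78 s is, by
construction, one traversing the field of view, not one parked at the
bottom wall. With `init = "uniform"` (also available) a fast sinker started
near the floor reflects immediately and its fitted velocity is biased low
for reasons unrelated to the estimators. Alumina at 2.36 µm/s covers
184 µm in 78 s, so uniform placement would clip ~18% of tracks this way.

What the generator does **not** model: hologram formation and
reconstruction artifacts, inter-particle hydrodynamics, motility, particle
shape, wall drag, convection or shear beyond a uniform drift, and
photophysics beyond Poisson shot noise in the rendered volumes. Passing
recovery tests therefore demonstrate that the estimators are correct for
the assumed physics, not that real reconstructions are free of systematic
tracking errors.

## Estimators and their numerical choices

* **Diffusivity** (`msd_diffusivity()`): unweighted through-origin fit of
  MSD($k\Delta t$) over lags 1–3, divided by $2\times$dims. Short lags are
  the standard bias–variance compromise. Lateral ensemble drift is
  estimated (`estimate_drift()`) as the mean frame-to-frame displacement
  over concurrent tracks and subtracted first; axial drift is the signal
  and is never subtracted.
* **Static-noise bias**: localization noise adds a constant
  $2\sigma^2$ per axis to every MSD point. With a through-origin fit this
  inflates $\hat D$ by $\sigma^2\sum_k\tau_k/\sum_k\tau_k^2$ — at the
  default $\sigma_{xy}$ and 15 fps, a large effect for micron particles
  ($4D\Delta t \approx 0.11$ µm² versus $4\sigma^2 = 0.16$ µm²). Sizes
  from diffusivity are therefore trustworthy only when the noise floor is
  small against $4D\Delta t$; the estimator checks in the test suite use
  noise-free tracks for exactly this reason, and density recovery uses the
  known/independently measured radius (`radius_source = "fixed"`), whose
  axial pathway is unbiased: OLS slopes are insensitive to iid noise.
* **Sizing histograms** (`walker_diameters()`): per-track
  maximum-likelihood diffusivity from squared 2-D step lengths
  (exponentially distributed with mean $4D\Delta t$, so
  $\hat D_{\mathrm{ML}} = \overline{\Delta r^2}/(4\Delta t)$), converted to
  diameters and binned at 0.1 µm. This is a per-track simplification of
  the full step-distribution deconvolution sometimes used for
  polydisperse sizing.
* **Axial velocity** (`z_velocity()`): OLS slope of z on t. Its variance on
  a diffusing track over duration $T$ is ≈ $4.8\,D/T$, which sets the
  observation times and ensemble sizes needed below.
* **Outlier filter** (`filter_outliers()`): per-track diffusivities above
  1.20 µm²/s are discarded by default — for micron-scale particles in
  water this flags broken or mislinked tracks, not physics.
* **Summaries** (`summarize_population()`): mean, median and Student-t 95%
  CI of the mean; medians are reported alongside because size and
  diffusivity distributions are skewed.
* **Degenerate inputs**: neutral buoyancy yields `Inf` timescales and
  Strouhal numbers (a documented sentinel, not an error) so density sweeps
  keep going; too-short tracks are flagged, not dropped silently.

## Tracking

Rendered volumes are max-projected (XYT for lateral motion; resliced XZT
for axial), thresholded (Otsu by default), labelled, and reduced to
intensity-weighted centroids (via `EBImage`), giving sub-pixel positions in
µm. Linking is greedy nearest-neighbour with distance gating and gap
closing over ≤ 2 missed frames: within a frame, candidate pairs are
accepted in order of increasing distance, ties to the lowest track id,
which makes the result invariant to detection order. At the particle
loadings the instrument targets (tens of particles per 356 µm field) greedy
association agrees with the brute-force optimal assignment, which the test
suite verifies by enumeration on 3-particle scenes and keeps only as an
oracle.

## Classification and planning

`classify_density()` applies the density gap to
$\hat\rho_p = \hat{\Delta\rho} + \rho_f$: below $\rho_f$ →
`buoyant-biological` (no mineral floats, so a floater is a high-confidence
biological call); below 1300 kg/m³ → `cell-like`; above 1500 kg/m³ →
`mineral-like`; the gap itself → `ambiguous`, an explicit output rather
than a forced call, consistent with a ~10% density uncertainty still
leaving the gap clear. Thresholds are configurable. Motion regimes use
$\mathrm{Sr}_p$ cut at 0.1 and 10 around the equal-importance point
$\mathrm{Sr}_p \sim 1$ (the literature gives only "~1" and "≪ 1"; the
decade margins are this package's choice, config-exposed).

`mission_plan()` turns the same physics into observation requirements: the
recording must last $t = d_{\mathrm{axial}}/|v|$ for the drift to exceed
the axial resolution, exactly linear in $1/g$. Resolving
$\Delta\rho = 100$ kg/m³ at $r = 0.75$ µm and $d = 2$ µm takes 16.3 s on
Earth (the analytic value; it is often quoted rounded to ~15 s), minutes on
Mars or Europa, and ~1400 s on Enceladus with ~1% of Earth's gravity —
long enough to constrain lander stability. Gravities used: Earth 9.81,
Mars 3.71, Europa 1.315, Enceladus 0.113 m/s² (standard values; they are
a configuration input, not a measurement).

```{r plan}
mission_plan(
  classes = tibble::tibble(label = "bacterium",
                           delta_rho_kg_m3 = 100, radius_um = 0.75),
  fluid = fluid_medium(293.15, 1.002e-3, 998))
```

## Problem sizes and what the tests show

The recovery simulations in the test suite and the acceptance script use
the population sizes the corresponding published summary statistics refer
to: 15 alumina-density tracks over 78 s, 1000 bacterial-density and 1000
polystyrene tracks over 60 s, 100 vesicle clusters over 54 s, and
100–400-track ensembles for the estimator-calibration properties. With the
OLS variance above, these sizes put the recovered means well inside their
quoted intervals (e.g. the bacterial density-difference mean carries a
±≈21 kg/m³ 95% CI at n = 1000, against a target interval of ±8 around
100 kg/m³, compared through combined intervals). Stochastic checks are
written against 3-standard-error bands with fixed seeds.

## Known limitations

* Diffusivity-derived sizes are biased upward under realistic localization
  noise (see above); an offset-aware MSD fit or covariance estimator is
  the natural extension but is deliberately out of scope.
* The Walker realisation here is per-track ML, not the full histogram
  deconvolution; very broad size mixtures will blur.
* No porosity model: loose aggregates (e.g. vesicle clusters) have
  effective densities between their material and the medium, so recovered
  $|\Delta\rho|$ can undershoot tabulated bulk values.
* Greedy linking can swap identities in dense fields or at high Strouhal
  mismatch between frame rate and motion; the gating defaults are tuned to
  sparse DHM fields.
* Stokes' law assumes spheres; elongated or rough grains settle slower
  than their volume-equivalent sphere, shifting $\hat{\Delta\rho}$ low.
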