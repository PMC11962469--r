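---
title: "The choanocyte-chamber pump model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The choanocyte-chamber pump model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Leuconoid sponges pump water through their bodies with near-spherical
choanocyte chambers: collar cells line the chamber wall, each with a single
flagellum pointing at the chamber center and carrying a traveling bending
wave that propagates radially inward. Water enters through many small
prosopyles in the wall and leaves through the single large apopyle, whose
half-opening angle we call `theta_a`. Two accessory structures shape the
flow: the reticulum, a gasket-like mesh connecting the collar tips, modelled
here as a concentric no-slip shell one collar length (8.2 um) inside the
wall, perforated by one aperture per flagellum; and the cone-cell ring, a
no-slip conical frustum joining the reticulum rim to the chamber rim at the
apopyle, which blocks backflow around the flagella.

All lengths are measured in flagellar arc lengths `L` (13 um for the
reference organism, the freshwater sponge *Ephydatia muelleri*), time in
beat periods `T`, and the viscosity is 1. The chamber radius is
`rho = R/L` in 1.5--3, the beat amplitude `A = 0.14 L`, and the flagellar
count `N` runs from tens to hundreds.

At these scales the Reynolds number is ~1e-4, so the fluid obeys the Stokes
equations and the flow is fully determined by the instantaneous boundary
velocities: flagellar nodes move with the prescribed beat, all surfaces are
at rest. We solve this resistance problem by collocation with regularized
Stokeslets: one regularized point force per surface-element centroid and
per flagellar node, with the blob width tied to the local spacing (half the
node spacing along flagella, half `sqrt(element area)` on surfaces). The
dense linear system is factorized directly. Field velocities and pressures
are superpositions of the regularized kernels, with pressure vanishing at
infinity.

Per time step (`dt = 0.02 T`, 50 steps per beat) we record:

* `Q` — the flux of `u . n` through a spherical cap spanning the apopyle
  (an integration surface only, no boundary condition);
* `Pc`, `Pmax` — the rescaled pressure at the chamber center and its
  maximum over a grid inside `0.5 R`;
* `W` — the flagellar rate of working `sum int u . f ds`.

Time averages over one period combine into the mechanical pumping
efficiency `eta = Qbar * Pmaxbar / Wbar`, the ratio of useful pumping power
(pressure rise times volumetric rate, with zero pressure at infinity) to
the power the flagella spend on the fluid.

## The flagellar waveform

The beat is a planar traveling wave in the plane spanned by the inward
radial axis and a transverse direction rotated by a per-flagellum angle
`psi`; beat phases `phi` are also per-flagellum. Ensemble members share one
chamber geometry and differ only in the seeded `psi`, `phi`.

Two waveform families are implemented. The default is an
arc-length-parameterized tangent-angle wave,
`tau(s, t) = Theta cos(k s - omega t + phi)`, integrated to a curve; it is
inextensible and base-clamped by construction, and `Theta` is calibrated so
the maximum lateral displacement equals `A`. The alternative
(`family = "projection"`) is the explicit sine `y = A sin(k x - omega t)`
with the axial span adjusted every instant so the arc length stays `L`.

The dimensionless wavenumber `kl` is defined throughout as the quantity an
experimenter measures from images: `2 l / lambda` in units of `pi`, with
`l` the projected length and `lambda` the projected wavelength. For the
projection family this equals `k l`; for the arclength family the projected
wavelength contracts by the same factor as the length, so it equals `k L`.

We chose the arclength family as the default because at the baseline
`kl = 3 pi` it gives a projected length `l ~ 0.88 L`, matching the measured
`l/L ~ 0.76` at `kl = 3.3 pi` and letting the flagellar tips pass the
reticulum shell as they do in the animal, whereas the constant-amplitude
sine compresses to `l ~ 0.48 L` and the tips would stop short of the shell.

One geometric fact limits every planar waveform: the arc length must cover
the total transverse travel `2 A` per half-wave, so `kl < pi L / (2 A)`,
about `3.6 pi` at `A = 0.14` (the arclength family reaches ~`4 pi` because
its amplitude grows from the clamped base). Published sweeps of this system
quote wavenumbers up to `6 pi` at the same amplitude; under strict
inextensibility those upper values are unreachable, and the package raises
an informative error rather than silently stretching the flagellum. Sweep
grids therefore stop at `3.5 pi`; the efficiency optimum near `3 pi` is
interior to the feasible range.

## Geometry and its free parameters

* **Prosopyles.** The anatomical prosopyle is 1--5 um across. With
  `prosopyle_mode = "total"` the carving removes randomly chosen wall
  triangles (away from flagellar bases) until the *total* open fraction of
  the sphere reaches ~1e-3; with `"per_hole"` each prosopyle has area
  `1e-3 * 4 pi R^2` (diameter 2.5 um at `rho = 1.5`, 4.9 um at `rho = 3`)
  and as many non-overlapping holes as possible are placed by seeded
  rejection sampling. The per-hole reading is the physically consistent
  one: a chamber whose total inlet is 1e-3 of its surface would choke
  (forcing the observed flow through it would take an interior pressure two
  orders of magnitude above what the flagella generate), while the per-hole
  reading yields both anatomically sized prosopyles and an inlet resistance
  consistent with the computed interior pressure and flow rate.
* **Reticulum apertures.** Each flagellum crosses the shell through a
  circular aperture of radius `1.2 A` (configurable), capped at 0.45 times
  the flagellar spacing on the shell so that dense chambers keep a
  connected shell: collar-tip openings abut, they do not merge.
* **Cone ring.** A no-slip frustum along the cone `theta = theta_a`
  between the reticulum and wall rims.
* **Flagellar bases.** A golden-angle spiral restricted to the zone outside
  the apopyle cap; deterministic given `(N, theta_a)`. A layout whose
  minimum spacing falls below `2 A x 0.7` is rejected as overpacked (the
  safety factor 0.7 admits the densest published chambers, whose beat
  envelopes just touch).

## Numerical choices

* Regularization factor 0.5x local spacing: a rigid translating sphere at
  ~700 collocation points recovers Stokes drag within 0.4%; larger factors
  degrade the drag and corrupt the near field where flagella thread the
  reticulum apertures.
* The no-slip condition holds at element centroids only, so the wall is
  porous at the element scale. Consequences we measured and accepted at the
  coarse tier (~500 wall elements): a fraction of the inlet flow enters
  between collocation points rather than through the carved prosopyles, and
  the outlet flow rate carries a beat-frequency oscillation from the
  random-phase flagellar ensemble that a watertight wall would damp. The
  period average `Qbar` is unaffected by the oscillation itself (it is
  periodic), and the net flux through any closed surface enclosing the
  chamber stays below 0.1% of the apopyle flux.
* Pressure sampling excludes grid points within 2.5 regularization lengths
  of any singularity; at smaller clearances the grid maximum reflects the
  kernel's self-signature rather than the smooth field (the clearance sweep
  plateaus at 2.5).
* Dense direct solves: the baseline chamber (N = 143, 10 nodes per
  flagellum, ~900 surface elements) has ~6,500 unknowns and solves in a few
  seconds per time step on one core.

## Resolution tiers and problem sizes

The package's own study sizes, chosen to keep a desk-scale budget: the
`coarse` tier (~500 wall triangles, 10 nodes per flagellum, 50 steps per
period) for baselines and acceptance runs; `paper` (~2000 triangles, 20
nodes) for convergence checks. Trend sweeps in the test suite run a
reduced protocol — about 350 wall triangles, 8 nodes, 10 time steps per
period, single seed, 4 grid points per axis — which resolves the
monotonicities and peak locations of the four parameter sweeps but not
their absolute values. The flux changes by under 10% between the coarse and
doubled tiers at a fixed beat phase.

## What the synthetic data do and do not emulate

`generate_morphometry()` draws per-chamber measurements from truncated
normals with the measured means and SDs (the published tables report only
mean +/- SD; normality is our assumption), enforcing positivity and apopyle
< chamber by rejection. `generate_waveform_tracks()` samples the model
waveform with isotropic positional noise, emulating digitized high-speed
imaging. They validate estimator recovery — not biology: real chambers are
not perfect spheres, real waveforms are not exactly periodic planar waves,
and real measurement error is not isotropic. Passing recovery tests shows
the estimators are consistent on the model class, nothing more.

## Known limitations

* The instantaneous outlet flow oscillates more than in a watertight
  boundary-element implementation (see above); single-period averages and
  multi-seed ensembles are the reported quantities. At the coarse tier the
  baseline chamber (`rho = 1.5`, `N = 143`, `theta_a = 30`, `kl = 3 pi`)
  averages `Qbar ~ 0.045 L^3/T` over a three-seed ensemble (recomputed by
  `scripts/acceptance.R`; individual seeds span roughly 0.035--0.06),
  i.e. ~2.6e3 um^3/s for a 13-um flagellum at 26 Hz — the experimentally
  estimated pumping rate of living chambers is of the same magnitude
  (4--5e3 um^3/s). Watertight boundary-element treatments of this geometry
  sit toward the upper end of that range; the collocation wall porosity
  and the coarse slender-body representation set this implementation's
  absolute flux scale.
* The apopyle-vs-prosopyle flux balance cannot be verified at feasible
  resolutions because part of the inlet flow is carried by the
  collocation-scale wall porosity; mass conservation is instead verified on
  closed surfaces enclosing the chamber.
* Elastohydrodynamics is out of scope: the beat shape is prescribed and
  assumed unaffected by the pressure difference, which is exactly the
  assumption behind the superposition treatment of an adverse pressure
  difference (`delta_p_response()`).
* The coarse-grained point-force chamber is a mechanism demonstrator for
  the `(1 + cos theta_a)` pressure geometry, not a quantitative surrogate.
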