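---
title: "Methods: Lagrangian larval dispersal and recruitment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Lagrangian larval dispersal and recruitment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pearldrift)
```

pearldrift simulates the planktonic phase of broadcast-spawning marine
invertebrates — the motivating case is the black-lip pearl oyster, whose
larvae drift for 26–30 days before becoming competent to settle — and asks
whether the cells where simulated particles accumulate predict where spat
collectors catch recruits. This vignette documents the model, the numerical
choices, the statistical arrangement, and what the synthetic test bed does
and does not establish.

## The advection–diffusion model

Particles are passive: no swimming, mortality, or settlement behaviour.
Per sub-step `dt` (seconds) a particle at (lon, lat) moves by

* an advective displacement `u_p * dt`, with `u_p` the surface current
  interpolated linearly in time between the two bracketing daily snapshots
  and bilinearly in space among the four surrounding grid nodes; and
* a turbulent displacement drawn as an isotropic 2-D random walk: with
  `R_NA`, `R_NB` uniform on (0, 1), radial magnitude
  `rho = sqrt(-4 * Eh * dt * log(1 - R_NA))` and angle `2 * pi * R_NB`.

The radial form deserves a note. The random-walk literature this
parameterisation descends from writes the turbulent kick so that its
mean-squared displacement is `4 * Eh * dt` (the defining property of a 2-D
walk with diffusivity `Eh`); the quantity `-4 Eh dt log(1 - R_NA)` has
units m², so the displacement is its square root — which is what
`diffusion_displacement()` implements, with the natural logarithm, and with
one shared radial magnitude paired with cos/sin for the two axes. The
closed form `E[-log(1 - R)] = 1` gives `E[rho^2] = 4 Eh dt` exactly, and a
Monte-Carlo test asserts this within 1 %, plus recovery of `Eh` from the
slope of positional variance against time (per-axis slope `2 Eh`).

Displacements in metres are converted to degrees on a spherical earth:
`dlat = dy / 111320`, `dlon = dx / (111320 * cos(lat))`. This
small-displacement approximation is consistent with a ~10 km grid and
sub-grid-spacing steps; it is exact for purely zonal motion at fixed
latitude and drifts by under 0.1 % over 60 days in the meridionally moving
test case.

### Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `Eh` | 5 | m² s⁻¹ | standard assumed horizontal eddy diffusivity for surface larval transport; unknown in the field, so treated as a tunable |
| `duration_days` | 60 | d | covers the 26–30 d pelagic larval duration plus a 30 d settlement window |
| seed days × per day | 10 × 202,240 | — | reference release protocol (2,022,400 total); desk-scale runs use 10 × 2,000 |
| `substep_safety` | 0.5 | — | fraction of the `dx`-bound used by the adaptive sub-step |
| `min_substep` | 60 | s | floor guarding pathological `u_max` |
| `recruitment_window` | (30, 60] | d | settlement-competent phase; early/late thirds are (30, 40] and (50, 60] |

### Sub-stepping, land and boundaries

The stepper recomputes `u_max` once per simulation day from that day's
snapshot and sets `dt = clamp(0.5 * dx_min / u_max, 60 s, 1 day)`, tiled
evenly into the day, so each advective sub-displacement stays below the
smallest node spacing. Three interaction rules are deliberate choices where
the source formulation is silent:

* **Interpolation near coasts** — land nodes contribute zero velocity to
  the bilinear stencil rather than being excluded and renormalised. Flow
  therefore damps smoothly toward the coast and interpolated velocities
  never extrapolate from land values.
* **Land hits** — a sub-displacement that would land on a land-masked node
  (nearest-node lookup) is cancelled; the particle holds position and
  remains active. This is the simplest non-absorbing rule and produces the
  coastal accumulation the visit maps are designed to show.
* **Domain exits** — a sub-displacement crossing the grid edge freezes the
  particle at its pre-step position with status `exited`; exited particles
  never re-enter and are excluded from visit counts. Queries exactly on the
  last grid column/row are inside (closed upper boundary).

Cohorts are released at the start of their day, before that day's
sub-steps; a particle released on day `d` appears first in the day-`d`
snapshot with age 0 and has age `D - d` on day `D`. The RNG stream order is
documented (per sub-step, per active particle in id order: `R_NA` then
`R_NB`), which lets a deliberately naive per-particle reference stepper
replay the batched implementation bit-for-bit — an oracle test, not a
convenience.

## Seeding

Seed points are uniform over the union of the seed polygons: a multinomial
allocation proportional to planar (degree-space) polygon areas, then
rejection sampling in each polygon's bounding box. Degree-space areas
slightly distort relative weights with latitude; over the <10° spans of
reef-habitat polygon sets the bias is negligible, and it is documented as a
limitation rather than corrected. Fresh positions are drawn for every
release day — the protocol fixes the seed *areas*, not the points — with a
flag to repeat day-0 positions for sensitivity checks. Polygon construction
from bathymetry is out of scope; polygons are inputs.

## Visit counting

A *visit* is one active particle in one daily snapshot. Counting per
snapshot (not per sub-step) makes totals independent of the adaptive `dt`,
and repeat occupancy is intentional — the quantity is cumulative visits,
a proxy for settlement opportunity, not unique-particle coverage. Cells are
half-open (`[west, east) × [south, north)`) so each position falls in
exactly one cell; a coordinate computed to sit exactly on a shared edge is
snapped (1e-9-cell tolerance) to the east/north cell. Windows are half-open
`(start, end]` in days, so day 30–40 spans 10 snapshots. Because it is
ambiguous whether "cumulative counts at day 60" should start at day 0 or at
day 30, both extracts (`cumulative60` and `full`) are always produced.

## The statistics

* **Correlation** — untransformed cumulative site counts against
  arcsinh-transformed spat counts (the transform is stated for the spat
  data only); `r`, `t = r sqrt(df/(1-r²))`, `df = n - 2`, two-sided p.
  At the reference network size, n = 28 sites gives df = 26.
* **Rank-sum** — Mann–Whitney U of the first (simulated) sample, midranks
  for ties, tie-adjusted variance, 0.5 continuity correction, normal
  two-sided p. Orientation matters when comparing W values across software;
  ours is documented and cross-checked against both `wilcox.test()` and
  exact enumeration for small samples.
* **Per-site t-tests** — the named procedure ("one-sample t-tests per
  site") does not specify how counts in the 10⁵–10⁶ range are compared to
  spat totals in the 10⁰–10³ range. Our arrangement z-standardises both
  vectors across sites (counts within each season, arcsinh-spat across
  sites) so they share a scale, then tests each site's seasonal values
  against its spat z-score. This is flagged as an interpretation;
  `standardize = FALSE` gives the raw test. Raw and Benjamini–Hochberg
  adjusted p-values are reported side by side.
* **Corridor matrix** — the "pairwise particle density" between sites is
  read as the median visit count over the cells crossed by the straight
  lon/lat segment between the pair (cells enumerated by splitting the
  segment at every cell-edge crossing), medianed across the supplied
  season × window grids; the diagonal is the site's own cell count.
* **Checks** — Shapiro–Wilk per sample (n restricted to 3–5000) and a
  median-centred (Brown–Forsythe) Levene test, hand-rolled as a one-way
  ANOVA on absolute deviations from group medians.

## The synthetic world

The generator exists so that every pipeline stage can be tested with known
structure; its defaults are chosen once:

* **Fields** — 50 × 50 nodes at 1/12°, daily snapshots, amplitude
  0.3 m s⁻¹ (a typical tropical surface-current magnitude). The default
  double-gyre regime is built by *discrete* central differences of the
  analytic streamfunction on an f-plane, so the discrete divergence of
  interior cells vanishes to floating point — retention and coastal
  accumulation then emerge from the flow, not from numerical sources or
  sinks. An AR(1) daily amplitude modulation (sd 0.1) and a per-season
  gyre phase make spawning seasons distinct forcing realisations.
* **Habitat** — annular polygons from just off each island coast to a
  0.15° buffer, emitted as single simple "keyhole" rings so the polygon
  validator's simple-ring invariant holds.
* **Spat counts** — a latent Gaussian tied to the standardised site counts
  at correlation ρ feeds an exponential link (`mu = 200 * exp(z)`) and a
  gamma–Poisson draw (dispersion 0.3). The link and count noise attenuate
  the realised correlation below ρ, so the generator estimates the
  attenuation by a fixed-substream Monte Carlo over the latent distribution
  and inflates the latent correlation accordingly; at ρ = 0.45 and n = 28
  the mean realised r across 500 replicates falls in the reported operating
  regime (0.40–0.50).

A green test suite on this world establishes that the numerics implement
the stated model (interpolation exactness, diffusion law, conservation,
determinism, oracle equivalence) and that the statistical machinery has its
nominal properties. It does **not** establish anything about real
geography: the synthetic gyre has none of the bathymetric steering,
tides, wind forcing, or ENSO-scale variability of a real hindcast, and the
headline field results (specific aggregation regions, retention
percentages, the observed r ≈ 0.43 against real collector data) depend on
the original forcing and field data, which are not redistributable here.
The percentage-difference and retention calculators are provided but not
held to those values.

## Known limitations

* Planar degree-space areas for seeding weights; spherical-earth constant
  111,320 m/degree throughout.
* Nearest-node land lookup means the effective coastline is a half-cell
  stairstep around the mask.
* The rank-sum W is convention-dependent; compare p-values, not W, across
  software.
* No netCDF bindings are available in the build environment, so gridded
  fields round-trip through a documented long-format CSV with
  HYCOM-convention variable names; the reader's variable-name map keeps the
  interface ready for a netCDF front end.
* One RNG stream drives seeding and turbulence; reproducibility is per
  (seed, schedule, field), not per particle.
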