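# pearldrift

Biophysical larval-dispersal modelling for broadcast-spawning marine
invertebrates, built around the spat-collection problem for the black-lip
pearl oyster (*Pinctada margaritifera*): where do passively drifting larvae
released from reef habitat end up, which coastal cells accumulate them
during the settlement-competent window, and do simulated aggregation
patterns agree with the numbers of spat that field collectors actually
catch?

The package is aimed at marine ecologists and aquaculture planners who want
a fully scripted, reproducible version of this workflow — simulation,
gridding and statistics — that runs at desk scale on synthetic forcing and
can be pointed at real gridded current products and collector tables.

## The model

Larvae are simulated as passive Lagrangian particles advected by daily
gridded surface currents. Per sub-step Δt the displacement of a particle at
position **x** is

    Δx = u_p Δt + K

where `u_p` is the surface current at the particle position (linear
interpolation in time between daily snapshots, then bilinear in lon/lat)
and `K` is an isotropic random-walk parameterisation of sub-grid
turbulence: with `R_NA`, `R_NB` uniform on (0, 1),

    ρ = sqrt(−4 E_h Δt ln(1 − R_NA)),   K = (ρ cos 2πR_NB, ρ sin 2πR_NB)

so that `E[ρ²] = 4 E_h Δt`, the mean-squared displacement of a 2-D walk
with horizontal eddy diffusivity `E_h` (default 5 m² s⁻¹). The sub-step is
chosen adaptively so the advective displacement stays below the grid
spacing (`Δx < dx`). Default protocol: particles seeded uniformly over
seed-area polygons every day for the first 10 days (202,240 per day at
reference scale, i.e. 2,022,400 in total), 60-day runs, no mortality or
competency behaviour.

Post-processing counts cumulative particle visits per forcing-grid cell
(~10 km² at 1/12°), extracts early (day 30–40), late (day 50–60) and full
(day 30–60) recruitment windows, and compares per-site counts with observed
spat totals via Pearson correlation (on arcsinh-transformed spat counts),
a continuity-corrected Wilcoxon rank-sum test, per-site one-sample t-tests,
Shapiro–Wilk/Levene checks, and a pairwise site-corridor density matrix.

Because no real hindcast or field data ship with the package, a
first-class synthetic module provides analytic current fields (constant,
zonal jet, divergence-free double gyre) with island land masks, annular
seed polygons, and an overdispersed spat-count generator whose correlation
with simulated site counts is calibrated to a target (default ρ = 0.45,
the regime reported in field comparisons).

## Worked example

```r
library(pearldrift)

field <- make_field(nx = 40, ny = 40, n_days = 60, regime = "double_gyre",
                    amplitude = 0.3,
                    islands = tibble::tibble(lon = 178.2, lat = -18.4, radius = 0.3),
                    noise_sd = 0.1, seed = 42)
field
#> <current_field> 40 x 40 nodes, 61 daily snapshots
#>   lon [177.0000, 180.2500] dx=0.083333 deg; lat [-19.5000, -16.2500]
#>   land fraction 2.5%, max speed 0.392 m/s

seeds    <- make_island_polygons(tibble::tibble(lon = 178.2, lat = -18.4, radius = 0.3),
                                 field, buffer_deg = 0.15)
schedule <- build_release_schedule(seed_days = 10, particles_per_day = 1000)
config   <- simulation_config(Eh = 5, duration_days = 60, rng_seed = 42)

traj  <- run_season_simulation(field, seeds, schedule, config)
grids <- window_counts(traj, field)
grids$cumulative60
#> <visit_grid> 40 x 40 cells, window (0, 60] days, total 543,615 visits

sites  <- make_collector_sites(field, n_sites = 28, seed = 42)
counts <- site_cell_count(grids$cumulative60, sites$lon, sites$lat)
spat   <- simulate_spat_counts(counts, rho = 0.45, seed = 42)
pearson_with_df(counts, arcsinh_transform(spat))
#> r(26) = 0.373, p = 0.0506, R^2 = 0.1392
```

The 10,000 released particles produced 543,615 cell visits over the 60
daily snapshots (each active particle contributes one visit per day); the
correlation line reads as in the field literature — 28 sites give 26
degrees of freedom, and this draw of the ρ = 0.45 spat generator realises
r = 0.373, explaining ~14 % of the variance in transformed spat counts.
`autoplot(grids$cumulative60)` renders the log-scale heat map;
`run_pipeline()` orchestrates multi-season runs, writes every grid, site
count and statistic to CSV, and records a checksummed manifest.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it builds the desk-scale synthetic scenario (three spawning seasons, 10
seed days × 2,000 particles, 60 days, 28 collector sites) from the given
seed, executes the full simulate → grid → stats pipeline, and writes the
report JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
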