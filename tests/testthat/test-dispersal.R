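test_that("adaptive sub-step follows the grid-spacing rule", {
  f <- make_field(nx = 8, ny = 8, n_days = 1, lon0 = 0, lat0 = 0,
                  regime = "constant", amplitude = 0)
  cfg <- simulation_config()
  # dx_min at the domain's extreme latitude; at ~0.6 deg it is ~9276 m
  dx_min <- min(grid_spacing_meters(f, max(abs(f$lat))),
                grid_spacing_meters(f, 0, "meridional"))
  expect_equal(compute_substep(f, cfg, 1.0), 0.5 * dx_min, tolerance = 1e-12)
  expect_lt(abs(compute_substep(f, cfg, 1.0) - 4638.3), 1)
  expect_equal(compute_substep(f, cfg, 0), 86400)
  # inverse proportionality until the floor
  expect_equal(compute_substep(f, cfg, 0.5), 2 * compute_substep(f, cfg, 1.0))
  expect_equal(compute_substep(f, cfg, 1e6), cfg$min_substep)
})

test_that("turbulent displacement has the prescribed radial law", {
  set.seed(31)
  expect_equal(diffusion_displacement(0, 1000, 5),
               cbind(dx_m = rep(0, 5), dy_m = rep(0, 5)))
  n <- 2e5
  d <- diffusion_displacement(5, 1000, n)
  # angular symmetry: mean displacement ~ (0,0) within 3 standard errors
  se <- sqrt(2 * 5 * 1000 / n)  # per-axis sd = sqrt(2 Eh dt)
  expect_lt(abs(mean(d[, 1])), 3 * se)
  expect_lt(abs(mean(d[, 2])), 3 * se)
  # E[rho^2] = 4 Eh dt within 1%
  msd <- mean(d[, 1]^2 + d[, 2]^2)
  expect_equal(msd, 4 * 5 * 1000, tolerance = 0.01)
})

test_that("advection converts metres to degrees correctly", {
  f <- constant_field(0, 0)
  cfg <- simulation_config(Eh = 0)
  ens <- active_ensemble(c(0, 0.5), c(0, 1))
  # stationarity with no flow and no diffusion
  out <- advance_particles(ens, f, cfg, 0, 1000)
  expect_equal(out$lon, ens$lon)
  expect_equal(out$lat, ens$lat)
  # u = 1 m/s at lat 0 for 1000 s -> dlon = 1000/111320 deg
  f1 <- constant_field(1, 0)
  out <- advance_particles(active_ensemble(0, 0), f1, cfg, 0, 1000)
  expect_equal(out$lon, 1000 / 111320, tolerance = 1e-12)
  expect_equal(out$lon, 0.0089831, tolerance = 1e-4)
})

test_that("particles crossing the boundary exit and freeze; land cancels the sub-step", {
  f1 <- constant_field(1, 0, nx = 6, ny = 6, dx_deg = 0.05)
  cfg <- simulation_config(Eh = 0)
  edge <- max(f1$lon) - 0.001
  out <- advance_particles(active_ensemble(edge, 0), f1, cfg, 0, 10000)
  expect_equal(out$status, "exited")
  expect_equal(out$lon, edge)  # frozen at the pre-step position
  # once exited, further stepping leaves the particle untouched
  out2 <- advance_particles(out, f1, cfg, 0.2, 10000)
  expect_identical(out2, out)

  # an island directly downstream cancels the displacement
  isl <- tibble::tibble(lon = 177.6, lat = -19.2, radius = 0.1)
  fl <- make_field(nx = 20, ny = 20, n_days = 2, lon0 = 177, lat0 = -19.6,
                   regime = "constant", amplitude = 1, islands = isl)
  start_lon <- 177.45
  out <- advance_particles(active_ensemble(start_lon, -19.2), fl,
                           simulation_config(Eh = 0), 0, 20000)
  expect_equal(out$status, "active")
  expect_equal(out$lon, start_lon)  # held position
})

test_that("a season run conserves particles, tracks ages and is deterministic", {
  f <- make_field(nx = 30, ny = 30, n_days = 12, regime = "double_gyre",
                  amplitude = 0.2)
  ps <- seed_polygons(list(rect_ring(177.8, 178.6, -19.0, -18.4)))
  sch <- build_release_schedule(4, 80)
  cfg <- simulation_config(Eh = 5, duration_days = 12, rng_seed = 77)
  traj <- run_season_simulation(f, ps, sch, cfg)

  # conservation at every snapshot: released rows + unreleased = total
  audit <- dplyr::count(traj, day)
  expect_equal(audit$day, 0:12)
  released_expected <- pmin((audit$day + 1), sch$seed_days) * sch$particles_per_day
  expect_equal(audit$n, released_expected)
  expect_true(all(traj$status %in% c("active", "exited")))

  # age = day - release_day for every released particle
  rel_day <- rep(sch$release_day_indices, each = sch$particles_per_day)
  expect_equal(traj$age, traj$day - rel_day[traj$particle_id])

  # identical seed -> identical trajectory
  traj2 <- run_season_simulation(f, ps, sch, cfg)
  expect_identical(as.data.frame(traj), as.data.frame(traj2))

  # forcing shorter than the duration fails before stepping
  expect_error(
    run_season_simulation(f, ps, sch, simulation_config(duration_days = 20)),
    "shorter", class = "pearldrift_validation_error"
  )
})

test_that("zero-velocity zero-diffusion runs leave every particle at its seed position", {
  f <- make_field(nx = 15, ny = 15, n_days = 6, regime = "constant", amplitude = 0)
  ps <- seed_polygons(list(rect_ring(177.3, 177.9, -19.3, -18.9)))
  sch <- build_release_schedule(2, 40)
  cfg <- simulation_config(Eh = 0, duration_days = 6, rng_seed = 5)
  traj <- run_season_simulation(f, ps, sch, cfg)
  first <- traj[traj$age == 0, ]               # each particle's release snapshot
  last <- traj[traj$day == 6, ]
  expect_equal(last$lon[match(first$particle_id, last$particle_id)], first$lon)
  expect_equal(last$lat[match(first$particle_id, last$particle_id)], first$lat)
  expect_true(all(last$status == "active"))
})

test_that("positional variance grows at 2*Eh per axis under pure diffusion", {
  f <- constant_field(0, 0)
  cfg <- simulation_config(Eh = 5)
  n <- 2e4
  set.seed(19)
  ens <- active_ensemble(rep(0, n), rep(0, n))
  vars <- matrix(NA_real_, 8, 2)
  for (d in 1:8) {
    ens <- advance_particles(ens, f, cfg, d - 1, 86400)
    vars[d, ] <- c(var(ens$lon * 111320 * cos(ens$lat * pi / 180)),
                   var(ens$lat * 111320))
  }
  t_s <- (1:8) * 86400
  eh_x <- unname(coef(lm(vars[, 1] ~ t_s))[2] / 2)
  eh_y <- unname(coef(lm(vars[, 2] ~ t_s))[2] / 2)
  expect_gt(eh_x, 4.5); expect_lt(eh_x, 5.5)
  expect_gt(eh_y, 4.5); expect_lt(eh_y, 5.5)
})
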