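#' Simulation configuration
#'
#' Parameters of the Lagrangian advection-diffusion stepper. Defaults
#' follow the reference configuration for passive bivalve larvae: a
#' horizontal turbulent diffusion coefficient of 5 m^2 s^-1, 60-day runs
#' (covering a 26-30 day pelagic larval duration plus a settlement window),
#' daily position snapshots, and a putative recruitment window of days
#' 30-60.
#'
#' The sub-step length is adapted once per simulation day so that the
#' advective displacement per sub-step stays below the grid spacing:
#' `dt = substep_safety * dx_min / u_max`, clamped to
#' `[min_substep, snapshot_interval]` and tiled evenly into the day.
#'
#' @param Eh Horizontal eddy diffusivity, m^2 s^-1 (>= 0).
#' @param duration_days Simulation length in days.
#' @param snapshot_interval Days between recorded snapshots (integer).
#' @param substep_safety Fraction of the grid-spacing bound used by the
#'   adaptive sub-step, in (0, 1].
#' @param min_substep Sub-step floor in seconds.
#' @param rng_seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param recruitment_window Two-day vector `(start, end]`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(Eh = 5, duration_days = 60, snapshot_interval = 1,
                              substep_safety = 0.5, min_substep = 60,
                              rng_seed = NULL, recruitment_window = c(30, 60)) {
  if (Eh < 0) abort("`Eh` must be >= 0.", class = "pearldrift_validation_error")
  if (duration_days < snapshot_interval) {
    abort("`duration_days` must be >= `snapshot_interval`.",
      class = "pearldrift_validation_error")
  }
  if (substep_safety <= 0 || substep_safety > 1) {
    abort("`substep_safety` must lie in (0, 1].", class = "pearldrift_validation_error")
  }
  if (snapshot_interval != floor(snapshot_interval) || snapshot_interval < 1) {
    abort("`snapshot_interval` must be a positive integer number of days.",
      class = "pearldrift_validation_error")
  }
  structure(
    list(
      Eh = Eh, duration_days = as.integer(duration_days),
      snapshot_interval = as.integer(snapshot_interval),
      substep_safety = substep_safety, min_substep = min_substep,
      rng_seed = rng_seed, recruitment_window = recruitment_window
    ),
    class = "simulation_config"
  )
}

#' Adaptive sub-step length
#'
#' Returns the sub-step `dt` (seconds) for the current simulation day:
#' `clamp(substep_safety * dx_min / u_max, min_substep, snapshot seconds)`,
#' where `dx_min` is the smallest node spacing (metres) over the field's
#' latitude range. With `u_max = 0` the full snapshot interval is returned.
#' By construction the advective displacement per sub-step never exceeds
#' `substep_safety * dx_min < dx_min`.
#'
#' @param field A [current_field()].
#' @param config A [simulation_config()].
#' @param u_max Maximum current speed for the day, m s^-1 (>= 0).
#' @return Sub-step length in seconds.
#' @export
compute_substep <- function(field, config, u_max) {
  stopifnot(u_max >= 0)
  snap_s <- config$snapshot_interval * 86400
  if (u_max == 0) return(snap_s)
  lat_ext <- max(abs(range(field$lat)))
  dx_min <- min(
    grid_spacing_meters(field, lat_ext, "zonal"),
    grid_spacing_meters(field, lat_ext, "meridional")
  )
  min(max(config$substep_safety * dx_min / u_max, config$min_substep), snap_s)
}

#' Random-walk turbulent displacement
#'
#' Sub-grid turbulence is modelled as an isotropic 2-D random walk. Per
#' draw, two uniform variates `R_NA`, `R_NB` in (0, 1) give a radial
#' magnitude `rho = sqrt(-4 * Eh * dt * ln(1 - R_NA))` and an angle
#' `2 * pi * R_NB`; the displacement is `(rho cos, rho sin)` metres. The
#' radial term has `E[rho^2] = 4 Eh dt`, the variance growth of a 2-D walk
#' with diffusivity `Eh` (per-axis variance `2 Eh dt`).
#'
#' Draw order is fixed and documented: for each particle in id order,
#' `R_NA` then `R_NB`, so that a per-particle reference stepper can replay
#' the stream of a batched one exactly.
#'
#' @param Eh Diffusivity, m^2 s^-1 (>= 0).
#' @param dt Sub-step length, seconds (> 0).
#' @param n Number of displacement draws.
#' @return An `n x 2` matrix (columns `dx_m`, `dy_m`), metres.
#' @export
diffusion_displacement <- function(Eh, dt, n = 1) {
  stopifnot(Eh >= 0, dt > 0, n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("dx_m", "dy_m"))))
  r <- runif(2 * n)
  rna <- r[seq(1, 2 * n, by = 2)]
  rnb <- r[seq(2, 2 * n, by = 2)]
  rho <- sqrt(-4 * Eh * dt * log(1 - rna))
  cbind(dx_m = rho * cos(2 * pi * rnb), dy_m = rho * sin(2 * pi * rnb))
}

# ---- internal ensemble state ----------------------------------------------
# plain vectors for speed; status codes 0 = unreleased, 1 = active, 2 = exited
STATUS_LEVELS <- c("unreleased", "active", "exited")

new_state <- function(schedule) {
  total <- schedule$total
  list(
    id = seq_len(total),
    lon = rep(NA_real_, total),
    lat = rep(NA_real_, total),
    age = rep(NA_real_, total),
    release_day = rep(schedule$release_day_indices, each = schedule$particles_per_day),
    status = rep(0L, total)
  )
}

state_to_tibble <- function(state) {
  tibble::tibble(
    particle_id = state$id, lon = state$lon, lat = state$lat,
    age = state$age, release_day = state$release_day,
    status = STATUS_LEVELS[state$status + 1L]
  )
}

tibble_to_state <- function(df) {
  df <- df[order(df$particle_id), ]
  list(
    id = df$particle_id, lon = df$lon, lat = df$lat, age = df$age,
    release_day = df$release_day,
    status = match(df$status, STATUS_LEVELS) - 1L
  )
}

# one sub-step on the internal state. Draws: runif(2 * n_active) interleaved
# (R_NA, R_NB per particle in id order).
step_state <- function(state, field, config, t, dt) {
  act <- which(state$status == 1L)
  if (!length(act)) return(state)
  lon <- state$lon[act]; lat <- state$lat[act]
  uv <- velocity_at_raw(field, lon, lat, t)
  disp <- diffusion_displacement(config$Eh, dt, length(act))
  dx_m <- uv$u * dt + disp[, 1]
  dy_m <- uv$v * dt + disp[, 2]
  new_lat <- lat + dy_m / METERS_PER_DEGREE
  new_lon <- lon + dx_m / (METERS_PER_DEGREE * cos(lat * pi / 180))
  if (any(!is.finite(new_lon)) || any(!is.finite(new_lat))) {
    abort("Non-finite particle position produced by the stepper.",
      class = "pearldrift_internal_error")
  }
  nx <- length(field$lon); ny <- length(field$lat)
  outside <- new_lon < field$lon[1] | new_lon > field$lon[nx] |
    new_lat < field$lat[1] | new_lat > field$lat[ny]
  # exits freeze at the pre-step position
  state$status[act[outside]] <- 2L
  inside <- !outside
  if (any(inside)) {
    landed <- is_land_at(field, new_lon[inside], new_lat[inside])
    move <- which(inside)[!landed]  # land hits cancel the sub-displacement
    state$lon[act[move]] <- new_lon[move]
    state$lat[act[move]] <- new_lat[move]
  }
  state
}

#' Advance an ensemble by one sub-step
#'
#' Applies one advection-diffusion sub-step to every active particle:
#' velocity sampled by [velocity_at()] at the particle position and time
#' `t`, a turbulent displacement from [diffusion_displacement()], metres
#' converted to degrees with the spherical-earth factors (`dlat = dy /
#' 111320`; `dlon = dx / (111320 cos lat)`). A displacement that would
#' leave the grid marks the particle `exited` and freezes it at its
#' pre-step position; a displacement onto a land-masked node is cancelled
#' for this sub-step (the particle holds position and stays active).
#' Unreleased and exited particles are unchanged.
#'
#' @param ensemble A particle tibble (columns `particle_id`, `lon`, `lat`,
#'   `age`, `release_day`, `status`).
#' @param field A [current_field()].
#' @param config A [simulation_config()].
#' @param t Current time, days.
#' @param dt Sub-step, seconds.
#' @return The updated ensemble tibble.
#' @export
advance_particles <- function(ensemble, field, config, t, dt) {
  state <- tibble_to_state(ensemble)
  state <- step_state(state, field, config, t, dt)
  state_to_tibble(state)
}

#' Run one spawning-season dispersal simulation
#'
#' Releases daily cohorts of uniformly seeded particles over the seed
#' polygons, advances them through the current field with the
#' advection-diffusion stepper, and records daily position snapshots. Day
#' `d` of the simulation proceeds as: release the day's cohort (if `d` is a
#' release day, positions drawn fresh by [sample_polygon_points()]), then
#' advance all active particles through the day's sub-steps; ages of all
#' released particles increment at the end of the day, so a particle
#' released on day `d` has age `D - d` in the day-`D` snapshot and appears
#' first (age 0) in that day's snapshot. Snapshot day 0 records the initial
#' cohort before any stepping. No mortality or
#' settlement competency is modelled.
#'
#' @param field A [current_field()] covering at least `duration_days`.
#' @param polyset A [seed_polygons()] set.
#' @param schedule A [build_release_schedule()].
#' @param config A [simulation_config()]; `config$rng_seed`, when non-NULL,
#'   seeds the single RNG stream used for seeding draws and turbulence.
#' @param repeat_day0_positions If `TRUE`, every cohort reuses the day-0
#'   positions instead of drawing fresh ones.
#' @param verbose Print a per-day audit line (day, active, exited counts).
#' @return A `trajectory_record`: a tibble with columns `day`,
#'   `particle_id`, `lon`, `lat`, `age`, `status`, one row per released
#'   particle per snapshot day.
#' @export
run_season_simulation <- function(field, polyset, schedule, config,
                                  repeat_day0_positions = FALSE, verbose = FALSE) {
  stopifnot(inherits(field, "current_field"), inherits(polyset, "seed_polygon_set"),
            inherits(schedule, "release_schedule"), inherits(config, "simulation_config"))
  if (max(field$time) - min(field$time) < config$duration_days) {
    abort("Forcing field is shorter than the simulation duration.",
      class = "pearldrift_validation_error")
  }
  if (schedule$seed_days > config$duration_days) {
    abort("`seed_days` exceeds the simulation duration.",
      class = "pearldrift_validation_error")
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  state <- new_state(schedule)
  snaps <- vector("list", config$duration_days + 1L)
  day0_pts <- NULL
  nt_index <- function(d) which.min(abs(field$time - d))

  release <- function(state, d) {
    cohort <- which(state$release_day == d & state$status == 0L)
    if (!length(cohort)) return(state)
    if (repeat_day0_positions && !is.null(day0_pts)) {
      pts <- day0_pts
    } else {
      pts <- sample_polygon_points(polyset, length(cohort))
      if (d == 0) day0_pts <<- pts
    }
    state$lon[cohort] <- pts$lon
    state$lat[cohort] <- pts$lat
    state$age[cohort] <- 0
    state$status[cohort] <- 1L
    state
  }

  record <- function(state, d) {
    rel <- which(state$status != 0L)
    tibble::tibble(
      day = d, particle_id = state$id[rel], lon = state$lon[rel],
      lat = state$lat[rel], age = state$age[rel],
      status = STATUS_LEVELS[state$status[rel] + 1L]
    )
  }

  state <- release(state, 0L)
  snaps[[1]] <- record(state, 0L)

  for (d in seq_len(config$duration_days) - 1L) {
    it <- nt_index(d)
    u_max <- max(sqrt(field$u[, , it]^2 + field$v[, , it]^2))
    dt_nom <- compute_substep(field, config, u_max)
    nsub <- ceiling(86400 / dt_nom)
    dt <- 86400 / nsub
    for (s in seq_len(nsub) - 1L) {
      state <- step_state(state, field, config, d + s * dt / 86400, dt)
    }
    rel <- state$status != 0L
    state$age[rel] <- state$age[rel] + 1
    # the next day's cohort enters at the start of day d+1, i.e. at the same
    # instant as the day-(d+1) snapshot, with age 0
    state <- release(state, d + 1L)
    if (verbose) {
      message(sprintf("  day %3d: active %d, exited %d, unreleased %d",
                      d + 1L, sum(state$status == 1L), sum(state$status == 2L),
                      sum(state$status == 0L)))
    }
    if ((d + 1L) %% config$snapshot_interval == 0L) {
      snaps[[d + 2L]] <- record(state, d + 1L)
    }
  }
  traj <- dplyr::bind_rows(snaps)
  class(traj) <- c("trajectory_record", class(traj))
  attr(traj, "schedule_total") <- schedule$total
  attr(traj, "duration_days") <- config$duration_days
  traj
}

#' Write a trajectory record to CSV
#'
#' @param traj A `trajectory_record` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(
    tibble::as_tibble(traj)[, c("day", "particle_id", "lon", "lat", "age", "status")],
    path, progress = FALSE
  )
  invisible(path)
}
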