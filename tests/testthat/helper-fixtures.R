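# shared fixtures: tiny analytic fields, simple polygons, and a deliberately
# naive one-particle-at-a-time reference stepper used as the oracle for the
# batched implementation

rect_ring <- function(lon0, lon1, lat0, lat1) {
  cbind(c(lon0, lon1, lon1, lon0), c(lat0, lat0, lat1, lat1))
}

# uniform constant-current field on a wide equatorial domain
constant_field <- function(u0 = 0.2, v0 = 0, nx = 40, ny = 40, n_days = 10,
                           dx_deg = 0.25, lon0 = -5, lat0 = -5) {
  lon <- lon0 + (seq_len(nx) - 1) * dx_deg
  lat <- lat0 + (seq_len(ny) - 1) * dx_deg
  time <- 0:n_days
  dims <- c(nx, ny, length(time))
  current_field(lon, lat, time, array(u0, dims), array(v0, dims))
}

# field linear in lon and lat: u = a*lon + b*lat, v = c*lon + d*lat
linear_field <- function(a = 0.1, b = -0.05, cc = 0, d = 0, nx = 10, ny = 10,
                         n_days = 4, dx_deg = 1 / 12, lon0 = 177, lat0 = -19) {
  lon <- lon0 + (seq_len(nx) - 1) * dx_deg
  lat <- lat0 + (seq_len(ny) - 1) * dx_deg
  time <- 0:n_days
  u2 <- outer(a * lon, b * lat, `+`)
  v2 <- outer(cc * lon, d * lat, `+`)
  u <- array(rep(u2, length(time)), c(nx, ny, length(time)))
  v <- array(rep(v2, length(time)), c(nx, ny, length(time)))
  current_field(lon, lat, time, u, v)
}

active_ensemble <- function(lon, lat, release_day = 0L) {
  n <- max(length(lon), length(lat))
  tibble::tibble(
    particle_id = seq_len(n), lon = rep_len(lon, n), lat = rep_len(lat, n),
    age = 0, release_day = release_day, status = "active"
  )
}

# reference stepper: per-particle scalar arithmetic, drawing R_NA then R_NB
# for each active particle in id order (the documented stream order)
naive_advance <- function(ensemble, field, config, t, dt) {
  ens <- ensemble[order(ensemble$particle_id), ]
  lon_min <- field$lon[1]; lon_max <- field$lon[length(field$lon)]
  lat_min <- field$lat[1]; lat_max <- field$lat[length(field$lat)]
  for (i in seq_len(nrow(ens))) {
    if (ens$status[i] != "active") next
    uv <- velocity_at(field, ens$lon[i], ens$lat[i], t)
    rna <- runif(1); rnb <- runif(1)
    rho <- sqrt(-4 * config$Eh * dt * log(1 - rna))
    dx_m <- uv$u * dt + rho * cos(2 * pi * rnb)
    dy_m <- uv$v * dt + rho * sin(2 * pi * rnb)
    new_lat <- ens$lat[i] + dy_m / 111320
    new_lon <- ens$lon[i] + dx_m / (111320 * cos(ens$lat[i] * pi / 180))
    if (new_lon < lon_min || new_lon > lon_max || new_lat < lat_min || new_lat > lat_max) {
      ens$status[i] <- "exited"
    } else {
      ix <- min(max(round((new_lon - lon_min) / field$dx_deg), 0), length(field$lon) - 1) + 1
      iy <- min(max(round((new_lat - lat_min) / field$dy_deg), 0), length(field$lat) - 1) + 1
      if (!field$land[ix, iy]) {
        ens$lon[i] <- new_lon
        ens$lat[i] <- new_lat
      }
    }
  }
  ens
}

# hand-built trajectory record (one row per particle per day)
manual_traj <- function(df) {
  traj <- tibble::as_tibble(df)
  class(traj) <- c("trajectory_record", class(traj))
  traj
}
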