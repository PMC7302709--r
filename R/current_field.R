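#' Gridded surface-current forcing
#'
#' A `current_field` holds daily snapshots of eastward (`u`) and northward
#' (`v`) surface velocity on a regular lon/lat grid, together with a land
#' mask. It is the hydrodynamic forcing that drives the Lagrangian particle
#' stepper: the hindcast products used for regional dispersal work (e.g.
#' HYCOM at 1/12 degree, daily output) have exactly this shape once a single
#' depth level is extracted.
#'
#' Velocities at land nodes are stored as zero and flagged in `land`, so
#' that spatial interpolation near the coast smoothly damps the flow toward
#' land instead of extrapolating from it.
#'
#' @param lon,lat Strictly increasing, uniformly spaced axes in decimal
#'   degrees.
#' @param time Integer-day axis (days since the simulation origin),
#'   uniformly spaced.
#' @param u,v Numeric arrays of dimension `c(length(lon), length(lat),
#'   length(time))`, in m s^-1. `NA` values mark land/invalid nodes.
#' @param land Optional logical `length(lon) x length(lat)` matrix; if
#'   omitted it is derived from non-finite velocity values (a node is land
#'   if its velocity is missing at any time).
#'
#' @return An object of class `current_field`: a list with elements `lon`,
#'   `lat`, `time`, `u`, `v` (land zeroed), `land`, `dx_deg`, `dy_deg`.
#' @export
current_field <- function(lon, lat, time, u, v, land = NULL) {
  check_axis(lon, "lon")
  check_axis(lat, "lat")
  check_axis(time, "time")
  dims <- c(length(lon), length(lat), length(time))
  if (!identical(dim(u), as.integer(dims))) {
    abort("`u` must have dimensions (lon, lat, time).", class = "pearldrift_validation_error")
  }
  if (!identical(dim(v), as.integer(dims))) {
    abort("`v` must have dimensions (lon, lat, time).", class = "pearldrift_validation_error")
  }
  bad <- !is.finite(u) | !is.finite(v)
  derived_land <- apply(bad, c(1, 2), any)
  if (is.null(land)) {
    land <- derived_land
  } else {
    if (!identical(dim(land), as.integer(dims[1:2]))) {
      abort("`land` must be a lon x lat logical matrix.", class = "pearldrift_validation_error")
    }
    land <- land | derived_land
  }
  # water nodes must be finite at all times
  water_bad <- bad & !array(rep(land, length(time)), dims)
  if (any(water_bad)) {
    abort("Non-finite velocity at water nodes.", class = "pearldrift_validation_error")
  }
  land_arr <- array(rep(land, length(time)), dims)
  u[land_arr] <- 0
  v[land_arr] <- 0
  structure(
    list(
      lon = as.numeric(lon), lat = as.numeric(lat), time = as.numeric(time),
      u = u, v = v, land = land,
      dx_deg = diff(lon[1:2]), dy_deg = diff(lat[1:2])
    ),
    class = "current_field"
  )
}

check_axis <- function(x, name) {
  if (length(x) < 2 || anyNA(x)) {
    abort(sprintf("Axis `%s` must have at least 2 finite values.", name),
      class = "pearldrift_validation_error")
  }
  d <- diff(x)
  if (any(d <= 0)) {
    abort(sprintf("Axis `%s` must be strictly increasing.", name),
      class = "pearldrift_validation_error")
  }
  if (max(abs(d - d[1])) > 1e-9 * max(abs(d[1]), 1)) {
    abort(sprintf("Axis `%s` is not uniformly spaced.", name),
      class = "pearldrift_validation_error")
  }
  invisible(x)
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf(
    "<current_field> %d x %d nodes, %d daily snapshots\n  lon [%.4f, %.4f] dx=%.6f deg; lat [%.4f, %.4f]\n  land fraction %.1f%%, max speed %.3f m/s\n",
    length(x$lon), length(x$lat), length(x$time),
    min(x$lon), max(x$lon), x$dx_deg, min(x$lat), max(x$lat),
    100 * mean(x$land), max(sqrt(x$u^2 + x$v^2))
  ))
  invisible(x)
}

#' Read / write a gridded current field
#'
#' The on-disk representation is a long-format CSV with one row per
#' (time, lat, lon) node and columns named by `var_map` (defaults follow
#' the HYCOM convention `lon`, `lat`, `time`, `water_u`, `water_v`).
#' Missing velocity values mark land nodes and become `land = TRUE`.
#'
#' @param path Path to a CSV file.
#' @param var_map Named list mapping the roles `lon`, `lat`, `time`, `u`,
#'   `v` to column names in the file.
#' @return `read_current_field()` returns a validated [current_field()];
#'   `write_current_field()` returns `path` invisibly.
#' @export
read_current_field <- function(path,
                               var_map = list(lon = "lon", lat = "lat", time = "time",
                                              u = "water_u", v = "water_v")) {
  if (!file.exists(path)) {
    abort(sprintf("Current-field file not found: %s", path), class = "pearldrift_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (role in c("lon", "lat", "time", "u", "v")) {
    nm <- var_map[[role]]
    if (is.null(nm) || !nm %in% names(df)) {
      abort(sprintf("Variable `%s` (role '%s') missing from %s.",
                    if (is.null(nm)) role else nm, role, path),
        class = "pearldrift_format_error")
    }
  }
  lon <- sort(unique(df[[var_map$lon]]))
  lat <- sort(unique(df[[var_map$lat]]))
  time <- sort(unique(df[[var_map$time]]))
  dims <- c(length(lon), length(lat), length(time))
  if (nrow(df) != prod(dims)) {
    abort("File does not contain a complete lon x lat x time grid.",
      class = "pearldrift_format_error")
  }
  ix <- match(df[[var_map$lon]], lon)
  iy <- match(df[[var_map$lat]], lat)
  it <- match(df[[var_map$time]], time)
  flat <- ix + (iy - 1L) * dims[1] + (it - 1L) * dims[1] * dims[2]
  u <- array(NA_real_, dims)
  v <- array(NA_real_, dims)
  u[flat] <- df[[var_map$u]]
  v[flat] <- df[[var_map$v]]
  current_field(lon, lat, time, u, v)
}

#' @param field A [current_field()].
#' @rdname read_current_field
#' @export
write_current_field <- function(field, path,
                                var_map = list(lon = "lon", lat = "lat", time = "time",
                                               u = "water_u", v = "water_v")) {
  stopifnot(inherits(field, "current_field"))
  dims <- dim(field$u)
  land3 <- array(rep(field$land, dims[3]), dims)
  u <- field$u; u[land3] <- NA_real_
  v <- field$v; v[land3] <- NA_real_
  df <- tibble::tibble(
    !!var_map$lon := rep(field$lon, times = dims[2] * dims[3]),
    !!var_map$lat := rep(rep(field$lat, each = dims[1]), times = dims[3]),
    !!var_map$time := rep(field$time, each = dims[1] * dims[2]),
    !!var_map$u := as.vector(u),
    !!var_map$v := as.vector(v)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# internal fast path: vectorised interpolation returning a list(u, v).
# Land nodes hold zero velocity, so they contribute (0,0) to the weighted
# sum by construction.
velocity_at_raw <- function(field, lon, lat, t) {
  nx <- length(field$lon); ny <- length(field$lat); nt <- length(field$time)
  fx <- (lon - field$lon[1]) / field$dx_deg
  fy <- (lat - field$lat[1]) / field$dy_deg
  dt_axis <- field$time[2] - field$time[1]
  ft <- (t - field$time[1]) / dt_axis
  ix <- pmin(pmax(floor(fx), 0), nx - 2)
  iy <- pmin(pmax(floor(fy), 0), ny - 2)
  it <- pmin(pmax(floor(ft), 0), nt - 2)
  wx <- fx - ix; wy <- fy - iy; wt <- ft - it
  base <- ix + 1 + iy * nx
  off_t0 <- it * (nx * ny)
  off_t1 <- off_t0 + nx * ny
  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy;       w11 <- wx * wy
  bil <- function(a, off) {
    w00 * a[base + off] + w10 * a[base + 1 + off] +
      w01 * a[base + nx + off] + w11 * a[base + nx + 1 + off]
  }
  list(
    u = (1 - wt) * bil(field$u, off_t0) + wt * bil(field$u, off_t1),
    v = (1 - wt) * bil(field$v, off_t0) + wt * bil(field$v, off_t1)
  )
}

#' Interpolate velocity at particle positions
#'
#' Linear interpolation in time between the two bracketing daily snapshots,
#' then bilinear interpolation in lon/lat among the four surrounding grid
#' nodes. Land nodes contribute zero velocity to the weighted sum, which
#' damps the interpolated flow toward the coast. Queries landing exactly on
#' the final grid column/row or final snapshot are treated as inside
#' (closed upper boundary).
#'
#' @param field A [current_field()].
#' @param lon,lat,t Vectors of query positions (degrees) and times (days);
#'   recycled to a common length.
#' @return A tibble with columns `u` and `v` (m s^-1), one row per query.
#' @export
velocity_at <- function(field, lon, lat, t) {
  stopifnot(inherits(field, "current_field"))
  n <- max(length(lon), length(lat), length(t))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t <- rep_len(t, n)
  out <- lon < field$lon[1] | lon > field$lon[length(field$lon)] |
    lat < field$lat[1] | lat > field$lat[length(field$lat)]
  out_t <- t < field$time[1] | t > field$time[length(field$time)]
  if (any(out | out_t)) {
    abort(sprintf("%d quer%s outside the %s extent of the field.",
                  sum(out | out_t), if (sum(out | out_t) == 1) "y lies" else "ies lie",
                  if (any(out)) "spatial" else "temporal"),
      class = "pearldrift_domain_error")
  }
  uv <- velocity_at_raw(field, lon, lat, t)
  tibble::tibble(u = uv$u, v = uv$v)
}

#' Grid node spacing in metres
#'
#' Converts the angular grid spacing to metres on a spherical earth
#' (111,320 m per degree), with zonal spacing scaled by `cos(lat)`. The
#' adaptive sub-stepping rule uses the minimum of the zonal and meridional
#' spacings over the active latitude range.
#'
#' @param field A [current_field()].
#' @param lat Latitude(s) in degrees, within \[-90, 90\].
#' @param direction `"zonal"` (east-west, default) or `"meridional"`.
#' @return Node spacing in metres (0 at the poles for the zonal direction;
#'   callers must guard).
#' @export
grid_spacing_meters <- function(field, lat, direction = c("zonal", "meridional")) {
  direction <- match.arg(direction)
  stopifnot(all(abs(lat) <= 90))
  if (direction == "zonal") {
    field$dx_deg * METERS_PER_DEGREE * cos(lat * pi / 180)
  } else {
    rep_len(field$dy_deg * METERS_PER_DEGREE, length(lat))
  }
}

# nearest-node land lookup (vectorised); positions assumed inside the grid
is_land_at <- function(field, lon, lat) {
  ix <- pmin(pmax(round((lon - field$lon[1]) / field$dx_deg), 0), length(field$lon) - 1) + 1
  iy <- pmin(pmax(round((lat - field$lat[1]) / field$dy_deg), 0), length(field$lat) - 1) + 1
  field$land[cbind(ix, iy)]
}
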