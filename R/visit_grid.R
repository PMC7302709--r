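#' Cumulative particle-visit grids
#'
#' A `visit_grid` accumulates cumulative particle-visit counts on the
#' forcing-resolution grid (1/12 degree cells are roughly 10 km^2 at
#' tropical latitudes). A visit is one active particle in one daily
#' snapshot: repeat occupancy counts every snapshot, and exited particles
#' are excluded. Cells are half-open, `[west, east) x [south, north)`, with
#' the cell's west/south edge on a grid node, so every position is counted
#' in exactly one cell and a point exactly on a shared edge belongs to the
#' east/north cell.
#'
#' @name visit_grid
NULL

new_visit_grid <- function(counts, field, window) {
  structure(
    list(
      counts = counts, lon = field$lon, lat = field$lat,
      dx_deg = field$dx_deg, dy_deg = field$dy_deg, window = window
    ),
    class = "visit_grid"
  )
}

#' @export
print.visit_grid <- function(x, ...) {
  cat(sprintf("<visit_grid> %d x %d cells, window (%g, %g] days, total %s visits\n",
              nrow(x$counts), ncol(x$counts), x$window[1], x$window[2],
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
#' @method as_tibble visit_grid
as_tibble.visit_grid <- function(x, ...) {
  tibble::tibble(
    lon = rep(x$lon, times = length(x$lat)),
    lat = rep(x$lat, each = length(x$lon)),
    count = as.vector(x$counts)
  )
}

# cell indices (1-based) of positions; half-open convention via floor, with
# a 1e-9-cell snap so points computed to sit exactly on a shared edge index
# into the east/north cell despite floating-point representation
cell_index <- function(grid, lon, lat) {
  fx <- (lon - grid$lon[1]) / grid$dx_deg
  fy <- (lat - grid$lat[1]) / grid$dy_deg
  ix <- floor(fx); ix <- as.integer(ix + (fx - ix > 1 - 1e-9)) + 1L
  iy <- floor(fy); iy <- as.integer(iy + (fy - iy > 1 - 1e-9)) + 1L
  list(ix = ix, iy = iy,
       inside = ix >= 1L & ix <= length(grid$lon) & iy >= 1L & iy <= length(grid$lat))
}

#' Accumulate particle visits over a day window
#'
#' For each snapshot day in the half-open window `(start, end]`, every
#' active particle increments the count of its containing cell by one.
#'
#' @param traj A `trajectory_record` from [run_season_simulation()].
#' @param field The [current_field()] whose grid defines the cells.
#' @param window Numeric `(start, end]` in days; defaults to the full
#'   record.
#' @return A `visit_grid`.
#' @export
accumulate_visits <- function(traj, field, window = NULL) {
  if (is.null(window)) window <- c(-Inf, max(traj$day, 0))
  nx <- length(field$lon); ny <- length(field$lat)
  counts <- matrix(0L, nx, ny)
  grid <- list(lon = field$lon, lat = field$lat,
               dx_deg = field$dx_deg, dy_deg = field$dy_deg)
  rows <- traj$day > window[1] & traj$day <= window[2] & traj$status == "active"
  if (!any(rows)) {
    warn("No active particle snapshots in the window; returning a zero grid.")
    return(new_visit_grid(counts, field, window))
  }
  ci <- cell_index(grid, traj$lon[rows], traj$lat[rows])
  flat <- ci$ix[ci$inside] + (ci$iy[ci$inside] - 1L) * nx
  tab <- tabulate(flat, nbins = nx * ny)
  counts <- matrix(as.integer(tab), nx, ny)
  new_visit_grid(counts, field, window)
}

#' Standard recruitment-window visit grids
#'
#' Computes the visit grids used in post-processing: the early (day
#' 30-40) and late (day 50-60) recruitment windows, the full recruitment
#' phase (day 30-60), and the day-60 cumulative grid from the start of the
#' run. All windows are half-open `(start, end]`.
#'
#' @inheritParams accumulate_visits
#' @param windows Named list of `(start, end]` pairs.
#' @return A named list of `visit_grid` objects.
#' @export
window_counts <- function(traj, field,
                          windows = list(early = c(30, 40), late = c(50, 60),
                                         full = c(30, 60), cumulative60 = c(0, 60))) {
  lapply(windows, function(w) accumulate_visits(traj, field, w))
}

#' Visit count of the cell containing a site
#'
#' @param grid A `visit_grid`.
#' @param lon,lat Site coordinates (degrees; vectors allowed).
#' @param name Optional site name(s), used in error messages.
#' @return Integer vector of cell counts, one per site.
#' @export
site_cell_count <- function(grid, lon, lat, name = NULL) {
  stopifnot(inherits(grid, "visit_grid"))
  ci <- cell_index(grid, lon, lat)
  if (any(!ci$inside)) {
    bad <- which(!ci$inside)[1]
    lab <- if (!is.null(name)) name[bad] else sprintf("(%.4f, %.4f)", lon[bad], lat[bad])
    abort(sprintf("Site %s lies outside the grid extent.", lab),
      class = "pearldrift_domain_error")
  }
  grid$counts[cbind(ci$ix, ci$iy)]
}

#' Per-site counts for a table of collector sites
#'
#' @param grids A named list of `visit_grid`s (e.g. from [window_counts()]).
#' @param sites A tibble with columns `name`, `lon`, `lat`.
#' @return A long tibble `name`, `window`, `count`.
#' @export
site_counts_table <- function(grids, sites) {
  purrr::imap_dfr(grids, function(g, w) {
    tibble::tibble(
      name = sites$name, window = w,
      count = site_cell_count(g, sites$lon, sites$lat, sites$name)
    )
  })
}

#' Export a cumulative heat-map series
#'
#' Writes cumulative visit grids (window `(0, d]`) at 5-day marks from day
#' 30 to day 60 as long-format CSV files `visits_day030.csv`, ..., plus
#' optional PNG heat maps on a log colour scale.
#'
#' @inheritParams accumulate_visits
#' @param out_dir Output directory (created if absent).
#' @param days Snapshot days to export.
#' @param png Also write PNG heat maps.
#' @return Tibble of written files (`day`, `path`), invisibly.
#' @export
export_heatmap_series <- function(traj, field, out_dir, days = seq(30, 60, by = 5),
                                  png = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory %s.", out_dir),
      class = "pearldrift_io_error")
  }
  files <- purrr::map_dfr(days, function(d) {
    g <- accumulate_visits(traj, field, c(0, d))
    path <- file.path(out_dir, sprintf("visits_day%03d.csv", d))
    readr::write_csv(as_tibble(g), path, progress = FALSE)
    if (png) {
      ggplot2::ggsave(sub("\\.csv$", ".png", path), autoplot(g),
                      width = 6, height = 5, dpi = 120)
    }
    tibble::tibble(day = d, path = path)
  })
  invisible(files)
}

#' Heat map of a visit grid
#'
#' @param object A `visit_grid`.
#' @param ... Unused.
#' @return A ggplot object (log10(count + 1) fill).
#' @export
#' @method autoplot visit_grid
autoplot.visit_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lon + object$dx_deg / 2, y = .data$lat + object$dy_deg / 2,
    fill = log10(.data$count + 1)
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10(visits + 1)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "Longitude", y = "Latitude",
      title = sprintf("Cumulative particle visits, days (%g, %g]",
                      object$window[1], object$window[2])
    )
}
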