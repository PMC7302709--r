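#' Seed-area polygon sets
#'
#' Natal reef habitat is represented as a set of simple closed rings of
#' (lon, lat) vertices — in field applications these are polygons mapped
#' from the shoreline out to a depth contour. Particles are released
#' uniformly over the union of the polygons, with per-polygon allocation
#' proportional to planar (degree-space) area; seed polygons typically span
#' well under ten degrees of latitude, so the distortion of degree-space
#' areas is small (a documented limitation).
#'
#' @param rings A list of numeric matrices, each `n x 2` (columns lon, lat,
#'   degrees) describing one simple closed ring; the closing vertex may be
#'   present or absent.
#' @return An object of class `seed_polygon_set`: a list with `rings`
#'   (unclosed vertex matrices) and `areas` (shoelace areas, degree^2).
#' @export
seed_polygons <- function(rings) {
  if (!is.list(rings) || length(rings) == 0) {
    abort("`rings` must be a non-empty list of vertex matrices.",
      class = "pearldrift_validation_error")
  }
  rings <- lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    if (is.data.frame(r)) r <- as.matrix(r[, 1:2])
    if (!is.matrix(r) || ncol(r) != 2 || !is.numeric(r)) {
      abort(sprintf("Ring %d is not an n x 2 numeric matrix.", i),
        class = "pearldrift_validation_error")
    }
    # drop an explicit closing vertex
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(unique(r)) < 3) {
      abort(sprintf("Ring %d has fewer than 3 distinct vertices.", i),
        class = "pearldrift_validation_error")
    }
    if (ring_self_intersects(r)) {
      abort(sprintf("Ring %d is self-intersecting.", i),
        class = "pearldrift_validation_error")
    }
    unname(r)
  })
  structure(
    list(rings = rings, areas = vapply(rings, shoelace_area, numeric(1))),
    class = "seed_polygon_set"
  )
}

#' @export
print.seed_polygon_set <- function(x, ...) {
  cat(sprintf("<seed_polygon_set> %d polygon(s), total planar area %.5f deg^2\n",
              length(x$rings), sum(x$areas)))
  invisible(x)
}

#' @export
#' @method as_tibble seed_polygon_set
#' @importFrom tibble as_tibble
as_tibble.seed_polygon_set <- function(x, ...) {
  purrr::map_dfr(seq_along(x$rings), function(i) {
    tibble::tibble(polygon = i, lon = x$rings[[i]][, 1], lat = x$rings[[i]][, 2])
  })
}

# unsigned shoelace area of an unclosed ring, in the units of its vertices
shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# proper-crossing test between all non-adjacent edge pairs; touching at
# shared endpoints is allowed (keyhole annuli have a narrow slit, not a
# zero-width one, so they pass)
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  a1 <- ring; a2 <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # edge n is adjacent to edge 1
    if (!length(js)) next
    if (any(segments_cross(a1[i, ], a2[i, ], a1[js, , drop = FALSE], a2[js, , drop = FALSE]))) {
      return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param lon,lat Query point coordinates (vectors, degrees).
#' @param ring An `n x 2` vertex matrix (unclosed simple ring).
#' @return Logical vector: `TRUE` where the point is inside.
#' @export
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Sample uniform points inside seed polygons
#'
#' Allocates `n` points across polygons by a multinomial draw with
#' probabilities proportional to planar polygon area, then rejection-samples
#' uniformly within each polygon's bounding box. A cap of 1e6 rejection
#' attempts per polygon guards degenerate slivers.
#'
#' @param polyset A [seed_polygons()] set.
#' @param n Number of points (>= 0).
#' @return A tibble with columns `lon`, `lat`, `polygon` (1-based index),
#'   in draw order.
#' @export
sample_polygon_points <- function(polyset, n) {
  stopifnot(inherits(polyset, "seed_polygon_set"))
  if (length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    abort("`n` must be a single non-negative integer.", class = "pearldrift_validation_error")
  }
  if (n == 0) {
    return(tibble::tibble(lon = numeric(), lat = numeric(), polygon = integer()))
  }
  areas <- polyset$areas
  if (any(areas == 0)) {
    warn(sprintf("%d zero-area polygon(s) skipped in seeding.", sum(areas == 0)))
  }
  if (all(areas == 0)) {
    abort("All seed polygons have zero area.", class = "pearldrift_validation_error")
  }
  alloc <- as.integer(rmultinom(1, n, prob = areas))
  pts <- vector("list", length(areas))
  for (k in seq_along(areas)) {
    if (alloc[k] == 0) next
    ring <- polyset$rings[[k]]
    bb <- c(range(ring[, 1]), range(ring[, 2]))
    got_lon <- numeric(0); got_lat <- numeric(0)
    attempts <- 0
    while (length(got_lon) < alloc[k]) {
      need <- alloc[k] - length(got_lon)
      batch <- max(need * 2L, 64L)
      if (attempts + batch > 1e6) {
        abort(sprintf("Rejection sampling exceeded 1e6 attempts for polygon %d.", k),
          class = "pearldrift_validation_error")
      }
      cx <- runif(batch, bb[1], bb[2])
      cy <- runif(batch, bb[3], bb[4])
      keep <- point_in_ring(cx, cy, ring)
      got_lon <- c(got_lon, cx[keep])
      got_lat <- c(got_lat, cy[keep])
      attempts <- attempts + batch
    }
    pts[[k]] <- tibble::tibble(
      lon = got_lon[seq_len(alloc[k])],
      lat = got_lat[seq_len(alloc[k])],
      polygon = k
    )
  }
  dplyr::bind_rows(pts)
}

#' Build a release schedule
#'
#' Cohorts of equal size are released at the start of each of the first
#' `seed_days` simulation days (day indices `0 .. seed_days - 1`). The
#' defaults reproduce the reference configuration of 10 seed days at
#' 202,240 particles per day, i.e. 2,022,400 particles in total.
#'
#' @param seed_days Number of daily release cohorts (>= 1).
#' @param particles_per_day Particles per cohort (>= 0).
#' @return An object of class `release_schedule` with fields `seed_days`,
#'   `particles_per_day`, `release_day_indices` and `total`.
#' @export
build_release_schedule <- function(seed_days = 10, particles_per_day = 202240) {
  for (nm in c("seed_days", "particles_per_day")) {
    x <- get(nm)
    if (length(x) != 1 || is.na(x) || !is.numeric(x) || x != floor(x)) {
      abort(sprintf("`%s` must be a single integer.", nm), class = "pearldrift_validation_error")
    }
  }
  if (seed_days < 1) {
    abort("`seed_days` must be >= 1.", class = "pearldrift_validation_error")
  }
  if (particles_per_day < 0) {
    abort("`particles_per_day` must be >= 0.", class = "pearldrift_validation_error")
  }
  structure(
    list(
      seed_days = as.integer(seed_days),
      particles_per_day = as.integer(particles_per_day),
      release_day_indices = seq_len(seed_days) - 1L,
      total = as.integer(seed_days) * as.integer(particles_per_day)
    ),
    class = "release_schedule"
  )
}

#' @export
print.release_schedule <- function(x, ...) {
  cat(sprintf("<release_schedule> %d day(s) x %d particles = %d total\n",
              x$seed_days, x$particles_per_day, x$total))
  invisible(x)
}

#' Read / write seed polygons as GeoJSON
#'
#' Reads the outer ring of every `Polygon` (and every part of a
#' `MultiPolygon`) from a GeoJSON file — either a bare geometry, a
#' `Feature`, or a `FeatureCollection`. Interior rings (holes) are ignored;
#' annular seed areas are represented as single keyhole rings by the
#' synthetic generator.
#'
#' @param path Path to a GeoJSON file.
#' @return `read_seed_polygons()` returns a [seed_polygons()] set;
#'   `write_seed_polygons()` returns `path` invisibly.
#' @export
read_seed_polygons <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Seed polygon file not found: %s", path), class = "pearldrift_io_error")
  }
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(
    g$type %||% "",
    FeatureCollection = lapply(g$features, function(f) f$geometry),
    Feature = list(g$geometry),
    Polygon = ,
    MultiPolygon = list(g),
    abort(sprintf("Unsupported GeoJSON type in %s.", path), class = "pearldrift_format_error")
  )
  rings <- list()
  for (geom in geoms) {
    coords <- switch(
      geom$type %||% "",
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      abort("Only Polygon/MultiPolygon geometries are supported.",
        class = "pearldrift_format_error")
    )
    for (poly in coords) {
      outer <- poly[[1]]  # outer ring only
      m <- do.call(rbind, lapply(outer, function(p) c(p[[1]], p[[2]])))
      rings[[length(rings) + 1L]] <- m
    }
  }
  seed_polygons(rings)
}

#' @param polyset A [seed_polygons()] set.
#' @rdname read_seed_polygons
#' @export
write_seed_polygons <- function(polyset, path) {
  stopifnot(inherits(polyset, "seed_polygon_set"))
  features <- lapply(polyset$rings, function(r) {
    closed <- rbind(r, r[1, ])
    list(
      type = "Feature",
      properties = stats::setNames(list(), character(0)),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(closed)), function(i) closed[i, ]))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
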