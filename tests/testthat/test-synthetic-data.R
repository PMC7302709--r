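test_that("constant and zonal regimes produce the advertised structure", {
  f0 <- make_field(nx = 8, ny = 8, n_days = 2, regime = "constant", amplitude = 0)
  expect_true(all(f0$u == 0) && all(f0$v == 0))
  fj <- make_field(nx = 12, ny = 12, n_days = 2, regime = "zonal_jet", amplitude = 0.4)
  expect_equal(max(fj$u), 0.4, tolerance = 1e-6)
  expect_true(all(fj$v == 0))
  # jet peaks at the central latitude
  peak_rows <- apply(fj$u[, , 1], 1, which.max)
  expect_true(all(abs(peak_rows - 6.5) < 1.5))
})

test_that("the double-gyre field is discretely divergence-free in the interior", {
  f <- make_field(nx = 30, ny = 30, n_days = 1, regime = "double_gyre", amplitude = 0.3)
  dxm <- f$dx_deg * 111320 * cos(mean(range(f$lat)) * pi / 180)
  dym <- f$dx_deg * 111320
  u <- f$u[, , 1]; v <- f$v[, , 1]
  # central-difference divergence over interior nodes (finite-difference oracle)
  i <- 3:(nrow(u) - 2); j <- 3:(ncol(u) - 2)
  div <- (u[i + 1, j] - u[i - 1, j]) / (2 * dxm) + (v[i, j + 1] - v[i, j - 1]) / (2 * dym)
  expect_lt(max(abs(div)), 1e-6 * 0.3 / dxm)
  expect_equal(max(sqrt(u^2 + v^2)), 0.3, tolerance = 1e-9)
})

test_that("island stencils mask approximately the right node count", {
  r <- 0.3; dx <- 1 / 12
  isl <- tibble::tibble(lon = 178.5, lat = -18.5, radius = r)
  f <- make_field(nx = 40, ny = 40, n_days = 1, islands = isl, regime = "constant",
                  amplitude = 0.1)
  expect_equal(sum(f$land), pi * r^2 / dx^2, tolerance = 0.1)
  expect_error(
    make_field(nx = 10, ny = 10, n_days = 1,
               islands = tibble::tibble(lon = 177, lat = -19.5, radius = 0.5)),
    "inside the domain", class = "pearldrift_validation_error"
  )
})

test_that("annular seed polygons sit on water and grow with the buffer", {
  isl <- tibble::tibble(lon = c(178.0, 179.0), lat = c(-18.5, -17.5),
                        radius = c(0.25, 0.2))
  f <- make_field(nx = 50, ny = 50, n_days = 1, islands = isl, regime = "constant",
                  amplitude = 0.1)
  ps <- make_island_polygons(isl, f, buffer_deg = 0.15)
  expect_equal(length(ps$rings), 2)
  for (k in 1:2) {
    vert <- ps$rings[[k]]
    expect_true(all(!pearldrift:::is_land_at(f, vert[, 1], vert[, 2])))
  }
  # area monotone in buffer width
  a1 <- sum(make_island_polygons(isl, f, buffer_deg = 0.10)$areas)
  a2 <- sum(make_island_polygons(isl, f, buffer_deg = 0.20)$areas)
  expect_gt(a2, a1)
  # seed points sampled from the annuli never fall on masked nodes
  set.seed(17)
  pts <- sample_polygon_points(ps, 1e4)
  expect_false(any(pearldrift:::is_land_at(f, pts$lon, pts$lat)))
})

test_that("synthetic spat counts are integers with a controllable correlation", {
  set.seed(70)
  sc <- runif(28, 1e5, 2e6)
  y <- simulate_spat_counts(sc, rho = 0.45, seed = 8)
  expect_type(y, "integer")
  expect_true(all(y >= 0))
  expect_error(simulate_spat_counts(sc, rho = 1), class = "pearldrift_validation_error")
  expect_error(simulate_spat_counts(sc, dispersion = 0), class = "pearldrift_validation_error")
  expect_error(simulate_spat_counts(rep(5, 28)), class = "pearldrift_validation_error")

  # null: signed mean correlation near zero over 300 replicates
  r0 <- vapply(1:300, function(i) {
    cor(sc, asinh(simulate_spat_counts(sc, rho = 0, seed = 3000 + i)))
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.06)

  # near-deterministic link: rho = 0.99, low dispersion
  r9 <- vapply(1:100, function(i) {
    cor(sc, asinh(simulate_spat_counts(sc, rho = 0.99, dispersion = 0.01,
                                       sigma_link = 1, seed = 4000 + i)))
  }, numeric(1))
  expect_gte(mean(r9 > 0.9), 0.95)
})

test_that("generated artifacts round-trip through the module readers", {
  td <- withr::local_tempdir()
  isl <- tibble::tibble(lon = 178.2, lat = -18.4, radius = 0.25)
  f <- make_field(nx = 25, ny = 25, n_days = 3, islands = isl,
                  path = file.path(td, "field.csv"))
  expect_equal(read_current_field(file.path(td, "field.csv"))$u, f$u)
  ps <- make_island_polygons(isl, f, path = file.path(td, "seeds.geojson"))
  expect_equal(read_seed_polygons(file.path(td, "seeds.geojson"))$rings, ps$rings)
  sites <- make_collector_sites(f, n_sites = 10, seed = 5)
  write_collector_sites(sites, file.path(td, "sites.csv"))
  expect_equal(read_collector_sites(file.path(td, "sites.csv")), sites)
})

test_that("collector sites land on water cells with unique names", {
  isl <- tibble::tibble(lon = 178.2, lat = -18.4, radius = 0.4)
  f <- make_field(nx = 40, ny = 40, n_days = 1, islands = isl)
  sites <- make_collector_sites(f, n_sites = 28, seed = 2)
  expect_equal(nrow(sites), 28)
  expect_false(anyDuplicated(sites$name) > 0)
  expect_false(any(pearldrift:::is_land_at(f, sites$lon, sites$lat)))
})
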