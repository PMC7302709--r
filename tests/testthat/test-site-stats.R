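test_that("arcsinh transform matches its closed form and preserves order", {
  expect_equal(arcsinh_transform(0), 0)
  expect_equal(arcsinh_transform(616), log(616 + sqrt(616^2 + 1)))
  expect_equal(arcsinh_transform(616), 7.1163, tolerance = 1e-4)
  set.seed(4)
  x <- sort(runif(50, 0, 1e4))
  expect_true(all(diff(arcsinh_transform(x)) > 0))
  expect_error(arcsinh_transform(-1), class = "pearldrift_validation_error")
  expect_error(arcsinh_transform(c(1, NA)), class = "pearldrift_validation_error")
})

test_that("pearson_with_df matches the from-definition computation and cor.test", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(pearson_with_df(y, 2 * y + 1)$r, 1)
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(28); z <- 0.4 * x + rnorm(28)
    res <- pearson_with_df(x, z)
    # independent oracle: sums-of-products definition
    r_def <- (sum(x * z) - length(x) * mean(x) * mean(z)) /
      sqrt((sum(x^2) - length(x) * mean(x)^2) * (sum(z^2) - length(x) * mean(z)^2))
    expect_equal(res$r, r_def, tolerance = 1e-12)
    ct <- cor.test(x, z)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p_two_sided, ct$p.value, tolerance = 1e-10)
    expect_equal(res$df, 26)
    expect_equal(res$r_squared, res$r^2)
  }
  expect_error(pearson_with_df(rep(1, 5), 1:5), class = "pearldrift_validation_error")
  expect_error(pearson_with_df(1:2, 1:2), class = "pearldrift_validation_error")
})

test_that("the correlation test has nominal type-I error under permutation", {
  set.seed(99)
  x <- rnorm(28)
  y <- rnorm(28)
  ps <- replicate(1e4, pearson_with_df(x, sample(y))$p_two_sided)
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("tidy and glance expose the correlation result; autoplot returns a ggplot", {
  res <- pearson_with_df(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  td <- tidy(res)
  expect_equal(td$estimate, res$r)
  expect_equal(td$parameter, 8)
  gl <- glance(res)
  expect_equal(gl$nobs, 10)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("rank-sum test matches wilcox.test and behaves at the extremes", {
  # completely separated samples: W at its extreme (0 with the lower sample first)
  rs <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rs$statistic, 0)
  expect_equal(rank_sum_test(c(10, 11, 12), c(1, 2, 3))$statistic, 9)
  # identical samples: no location shift
  rs0 <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(rs0$p_value, 0.9)
  # agreement with the standard implementation, including ties
  set.seed(12)
  for (i in 1:10) {
    x <- sample(1:6, 9, replace = TRUE)
    y <- sample(2:8, 7, replace = TRUE)
    rs <- rank_sum_test(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(rs$statistic, unname(wt$statistic))
    expect_equal(rs$p_value, wt$p.value, tolerance = 1e-10)
  }
  expect_error(rank_sum_test(rep(2, 4), rep(2, 3)), class = "pearldrift_validation_error")
  expect_error(rank_sum_test(numeric(0), 1:3), class = "pearldrift_validation_error")
})

test_that("per-site t-tests reproduce hand computations and flag degenerate sites", {
  # crafted site {2,4,6} vs mu0 = 0 -> t = 4/sqrt(4/3), df = 2
  counts <- tibble::tibble(
    name = rep(c("a", "b"), each = 3), season = rep(1:3, 2),
    count = c(2, 4, 6, 5, 5, 5)
  )
  spat <- tibble::tibble(name = c("a", "b"), spat = c(0, 0))
  res <- per_site_t_tests(counts, spat, standardize = FALSE)
  expect_equal(res$t[res$name == "a"], 4 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(res$t[res$name == "a"], 3.4641, tolerance = 1e-4)
  expect_equal(res$df[res$name == "a"], 2)
  # cross-check against stats::t.test
  tt <- t.test(c(2, 4, 6), mu = 0)
  expect_equal(res$t[res$name == "a"], unname(tt$statistic))
  expect_equal(res$p[res$name == "a"], tt$p.value)
  # zero across-season variance -> flagged, p omitted
  expect_true(is.na(res$t[res$name == "b"]))
  expect_match(res$note[res$name == "b"], "zero")
  # symmetric case: values {1,2,3} against their own mean -> t = 0, p = 1
  counts2 <- tibble::tibble(name = "c", season = 1:3, count = c(1, 2, 3))
  res2 <- per_site_t_tests(counts2, tibble::tibble(name = "c", spat = sinh(2)),
                           standardize = FALSE)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("normality and variance checks behave under known distributions", {
  # null coverage: standard-normal samples rarely rejected
  set.seed(41)
  p_null <- replicate(1000, shapiro.test(rnorm(28))$p.value)
  expect_gt(mean(p_null > 0.05), 0.9)
  # the report wires the same test through the package surface
  rep1 <- normality_and_variance_checks(list(g1 = rnorm(28), g2 = rnorm(28)))
  expect_named(rep1$shapiro, c("sample", "n", "W", "p"))
  # power against a heavily skewed sample
  set.seed(42)
  rejections <- replicate(200, {
    normality_and_variance_checks(list(e = rexp(200)))$shapiro$p < 0.05
  })
  expect_gt(mean(rejections), 0.95)
  # identical groups -> Levene statistic 0
  lev <- levene_test(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_equal(lev$statistic, 0)
  # agreement with the one-way ANOVA formulation on |x - median|
  set.seed(43)
  g1 <- rnorm(20); g2 <- rnorm(25, sd = 3)
  lev2 <- levene_test(list(g1, g2))
  z <- c(abs(g1 - median(g1)), abs(g2 - median(g2)))
  fit <- anova(lm(z ~ factor(rep(1:2, c(20, 25)))))
  expect_equal(lev2$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(lev2$p, fit$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(normality_and_variance_checks(list(a = 1:2)),
               class = "pearldrift_validation_error")
})

test_that("corridor density matrix matches hand-enumerated traversals", {
  f <- make_field(nx = 12, ny = 12, n_days = 1, regime = "constant", amplitude = 0)
  g <- accumulate_visits(
    manual_traj(tibble::tibble(day = 1, particle_id = 1L, lon = 177.01,
                               lat = -19.45, age = 1, status = "active")),
    f, c(0, 1)
  )
  # craft counts: three cells on one row hold {5, 9, 7}
  g$counts[] <- 0L
  g$counts[4, 6] <- 5L; g$counts[5, 6] <- 9L; g$counts[6, 6] <- 7L
  lon_mid <- function(i) f$lon[i] + f$dx_deg / 2
  lat_mid <- function(j) f$lat[j] + f$dy_deg / 2
  sites <- tibble::tibble(
    name = c("west", "east"),
    lon = c(lon_mid(4), lon_mid(6)), lat = c(lat_mid(6), lat_mid(6))
  )
  M <- pairwise_corridor_density(list(g), sites)
  expect_equal(unname(M["west", "east"]), 7)     # median of {5, 9, 7}
  expect_equal(unname(M["west", "west"]), 5)     # own cell
  expect_true(isSymmetric(unclass(M)))

  # two sites in the same cell -> the cell's count; uniform grid -> constant
  same <- tibble::tibble(name = c("p", "q"), lon = lon_mid(5) + c(0, 0.01),
                         lat = lat_mid(6))
  expect_equal(unname(pairwise_corridor_density(list(g), same)["p", "q"]), 9)
  g$counts[] <- 3L
  M3 <- pairwise_corridor_density(list(g), sites)
  expect_true(all(M3 == 3))
})

test_that("corridor matrices are symmetric and non-negative on random grids", {
  f <- make_field(nx = 15, ny = 15, n_days = 1, regime = "constant", amplitude = 0)
  set.seed(61)
  for (i in 1:3) {
    g <- accumulate_visits(
      manual_traj(tibble::tibble(day = 1, particle_id = 1L, lon = 177.2,
                                 lat = -19.2, age = 1, status = "active")),
      f, c(0, 1)
    )
    g$counts <- matrix(rpois(15 * 15, 40), 15, 15)
    sites <- tibble::tibble(
      name = paste0("s", 1:5),
      lon = runif(5, min(f$lon) + 0.1, max(f$lon) - 0.1),
      lat = runif(5, min(f$lat) + 0.1, max(f$lat) - 0.1)
    )
    M <- pairwise_corridor_density(list(g), sites)
    expect_true(isSymmetric(unclass(M)))
    expect_true(all(M >= 0))
  }
})
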