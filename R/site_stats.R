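#' Inverse hyperbolic sine transform
#'
#' `arcsinh(x) = ln(x + sqrt(x^2 + 1))`: a variance-stabilising transform
#' for overdispersed count data that, unlike the log, is defined at zero.
#' Applied to observed spat-recruitment counts before correlation against
#' simulated visit counts.
#'
#' @param x Non-negative finite numeric vector.
#' @return `asinh(x)`, elementwise.
#' @export
arcsinh_transform <- function(x) {
  if (any(!is.finite(x))) {
    abort("Inputs must be finite.", class = "pearldrift_validation_error")
  }
  if (any(x < 0)) {
    abort("Counts must be non-negative.", class = "pearldrift_validation_error")
  }
  asinh(x)
}

#' Pearson correlation with degrees of freedom
#'
#' Product-moment correlation between simulated site visit counts and
#' (transformed) observed spat counts, with the t-based two-sided test:
#' `t = r sqrt(df / (1 - r^2))`, `df = n - 2`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, both with non-zero
#'   variance.
#' @return A `correlation_result`: list with `r`, `df`, `t_stat`,
#'   `p_two_sided`, `r_squared`, `n` (and the data, for plotting).
#' @export
pearson_with_df <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    abort("`x` and `y` must have equal length n >= 3.",
      class = "pearldrift_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for zero-variance input.",
      class = "pearldrift_validation_error")
  }
  xm <- x - mean(x); ym <- y - mean(y)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  df <- n - 2
  t_stat <- r * sqrt(df / (1 - r^2))
  structure(
    list(
      r = r, df = df, t_stat = t_stat,
      p_two_sided = 2 * pt(-abs(t_stat), df),
      r_squared = r^2, n = n, x = x, y = y
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, p = %.3g, R^2 = %.4f\n", x$df, x$r, x$p_two_sided, x$r_squared))
  invisible(x)
}

#' @export
#' @method tidy correlation_result
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, statistic = x$t_stat, p.value = x$p_two_sided,
    parameter = x$df, r.squared = x$r_squared
  )
}

#' @export
#' @method glance correlation_result
glance.correlation_result <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r_squared, p.value = x$p_two_sided,
                 df = x$df, nobs = x$n)
}

#' @export
#' @method autoplot correlation_result
autoplot.correlation_result <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "Simulated site visit count", y = "arcsinh(observed spat count)",
      title = sprintf("r(%d) = %.3f, p = %.3g", object$df, object$r, object$p_two_sided)
    )
}

#' Wilcoxon rank-sum test (normal approximation, continuity corrected)
#'
#' Compares simulated and observed count samples by location. The
#' statistic `W` is the Mann-Whitney U of the first sample (rank sum of
#' `x` in the pooled midranked data minus `m(m+1)/2`); for completely
#' separated samples it attains 0 or `m * n` depending on which sample is
#' lower. The two-sided p-value uses the normal approximation with a 0.5
#' continuity correction and the tie-adjusted variance.
#'
#' @param x,y Non-empty numeric samples (simulated first).
#' @return A list with `statistic` (W), `p_value`, `m`, `n`.
#' @export
rank_sum_test <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) {
    abort("Both samples must be non-empty.", class = "pearldrift_validation_error")
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    abort("All values identical: rank-sum variance is degenerate.",
      class = "pearldrift_validation_error")
  }
  rk <- rank(pooled)  # midranks for ties
  W <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n
  ties <- table(pooled)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- W - m * n / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  structure(
    list(statistic = W, p_value = min(1, 2 * pnorm(-abs(z))), m = m, n = n),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum (continuity corrected): W = %g, p = %.3g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Per-site one-sample t-tests
#'
#' For each site, tests whether the site's across-season simulated counts
#' differ from its observed spat level. Because particle visits and spat
#' counts live on incommensurate scales, both vectors are z-standardised
#' across sites first (counts within each season; arcsinh-spat across
#' sites), an explicit interpretation choice; `standardize = FALSE` tests
#' the raw values against the raw reference.
#'
#' @param seasonal_counts Long tibble `name`, `season`, `count` (>= 2
#'   seasons per site).
#' @param spat Tibble `name`, `spat` (one row per site).
#' @param standardize Standardise both datasets across sites first.
#' @return Tibble `name`, `mean_count`, `reference`, `t`, `df`, `p`,
#'   `p_adj` (Benjamini-Hochberg), with `t`/`p` `NA` and a `note` for
#'   zero-variance sites.
#' @export
per_site_t_tests <- function(seasonal_counts, spat, standardize = TRUE) {
  stopifnot(all(c("name", "season", "count") %in% names(seasonal_counts)),
            all(c("name", "spat") %in% names(spat)))
  df <- seasonal_counts
  ref <- tibble::tibble(name = spat$name, ref = arcsinh_transform(spat$spat))
  if (standardize) {
    df <- df |>
      dplyr::group_by(.data$season) |>
      dplyr::mutate(count = as.numeric(scale(.data$count))) |>
      dplyr::ungroup()
    ref$ref <- as.numeric(scale(ref$ref))
  }
  res <- df |>
    dplyr::left_join(ref, by = "name") |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      n_seasons = dplyr::n(),
      mean_count = mean(.data$count),
      reference = .data$ref[1],
      s = sd(.data$count),
      .groups = "drop"
    )
  if (any(res$n_seasons < 2)) {
    abort("Each site needs at least 2 seasonal values.",
      class = "pearldrift_validation_error")
  }
  res |>
    dplyr::mutate(
      t = ifelse(.data$s > 0,
                 (.data$mean_count - .data$reference) / (.data$s / sqrt(.data$n_seasons)),
                 NA_real_),
      df = .data$n_seasons - 1,
      p = ifelse(is.na(.data$t), NA_real_, 2 * pt(-abs(.data$t), .data$n_seasons - 1)),
      p_adj = p.adjust(.data$p, method = "BH"),
      note = ifelse(is.na(.data$t), "zero across-season variance", "")
    ) |>
    dplyr::select(-"s", -"n_seasons")
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk on each sample (valid for n in 3..5000) and a
#' median-centred Levene (Brown-Forsythe) test across all samples.
#'
#' @param samples Named list of numeric vectors.
#' @return List with `shapiro` (tibble `sample`, `n`, `W`, `p`) and
#'   `levene` (list `statistic`, `df1`, `df2`, `p`).
#' @export
normality_and_variance_checks <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1)
  ns <- lengths(samples)
  if (any(ns < 3 | ns > 5000)) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000 per sample.",
      class = "pearldrift_validation_error")
  }
  sw <- purrr::imap_dfr(samples, function(x, nm) {
    s <- shapiro.test(x)
    tibble::tibble(sample = nm, n = length(x),
                   W = unname(s$statistic), p = s$p.value)
  })
  lev <- levene_test(samples)
  list(shapiro = sw, levene = lev)
}

#' Median-centred Levene test
#'
#' Brown-Forsythe variant: one-way ANOVA on absolute deviations from the
#' group medians.
#'
#' @param samples Named list of numeric vectors (>= 2 groups for a test;
#'   with 1 group the statistic is `NA`).
#' @return List `statistic`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(samples) {
  k <- length(samples)
  z <- lapply(samples, function(x) abs(x - median(x)))
  if (k < 2) return(list(statistic = NA_real_, df1 = NA, df2 = NA, p = NA_real_))
  zall <- unlist(z, use.names = FALSE)
  grp_n <- lengths(z)
  grp_mean <- vapply(z, mean, numeric(1))
  gm <- mean(zall)
  N <- sum(grp_n)
  ss_between <- sum(grp_n * (grp_mean - gm)^2)
  ss_within <- sum(vapply(z, function(zz) sum((zz - mean(zz))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0) {
    stat <- if (ss_between == 0) 0 else Inf
  } else {
    stat <- (ss_between / df1) / (ss_within / df2)
  }
  p <- if (is.finite(stat)) pf(stat, df1, df2, lower.tail = FALSE) else 0
  list(statistic = stat, df1 = df1, df2 = df2, p = p)
}

# cells traversed by the straight lon/lat segment between two points:
# split the segment at every cell-edge crossing and take the cell of each
# sub-interval midpoint
corridor_cells <- function(grid, p1, p2) {
  ci <- cell_index(grid, c(p1[1], p2[1]), c(p1[2], p2[2]))
  if (any(!ci$inside)) {
    abort("Corridor endpoint outside the grid extent.", class = "pearldrift_domain_error")
  }
  edge_ts <- function(a, b, origin, step) {
    if (a == b) return(numeric(0))
    ks <- seq(ceiling(min(a, b) / step - origin / step), floor(max(a, b) / step - origin / step))
    ts <- (origin + ks * step - a) / (b - a)
    ts[ts > 0 & ts < 1]
  }
  ts <- sort(unique(c(0, 1,
                      edge_ts(p1[1], p2[1], grid$lon[1], grid$dx_deg),
                      edge_ts(p1[2], p2[2], grid$lat[1], grid$dy_deg))))
  mid <- (head(ts, -1) + tail(ts, -1)) / 2
  mlon <- p1[1] + mid * (p2[1] - p1[1])
  mlat <- p1[2] + mid * (p2[2] - p1[2])
  cm <- cell_index(grid, mlon, mlat)
  unique(cbind(cm$ix, cm$iy))
}

#' Pairwise site-corridor particle density matrix
#'
#' For each pair of collector sites, samples the visit-grid cells crossed
#' by the straight lon/lat segment between them, takes the median cell
#' count per grid (season x window), and summarises each pair as the
#' median across all supplied grids. The diagonal holds the median (across
#' grids) of each site's own cell count. This corridor reading quantifies
#' particle densities along the path between site pairs.
#'
#' @param grids A list of `visit_grid`s (e.g. early and late windows for
#'   each season), all on the same cell layout.
#' @param sites Tibble `name`, `lon`, `lat` (>= 2 sites).
#' @return A symmetric `site x site` matrix of class
#'   `pairwise_density_matrix`.
#' @export
pairwise_corridor_density <- function(grids, sites) {
  stopifnot(length(grids) >= 1, nrow(sites) >= 2)
  ns <- nrow(sites)
  M <- matrix(0, ns, ns, dimnames = list(sites$name, sites$name))
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      vals <- vapply(grids, function(g) {
        cells <- corridor_cells(g, c(sites$lon[i], sites$lat[i]),
                                c(sites$lon[j], sites$lat[j]))
        median(g$counts[cells])
      }, numeric(1))
      M[i, j] <- M[j, i] <- median(vals)
    }
  }
  structure(M, class = c("pairwise_density_matrix", class(M)))
}

#' @export
#' @method autoplot pairwise_density_matrix
autoplot.pairwise_density_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("site_a", "site_b", "density")
  ggplot2::ggplot(df, ggplot2::aes(.data$site_a, .data$site_b, fill = log10(.data$density + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(median + 1)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise corridor particle density")
}
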