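#' Pipeline run configuration
#'
#' Bundles the inputs of a full simulate -> grid -> stats run. `field`,
#' `seeds` and `sites` may each be a path (CSV field, GeoJSON polygons,
#' CSV site table — validated to exist at configuration time) or an
#' already-loaded object; `field` may also be a named list of one
#' [current_field()] per season. Every referenced path must exist when the
#' config is built (fail-fast: no compute starts on a malformed run).
#'
#' @param field A [current_field()], list of them (one per season), or a
#'   CSV path.
#' @param seeds A [seed_polygons()] set or a GeoJSON path.
#' @param sites A site tibble (`name`, `lon`, `lat`, optionally `spat`) or
#'   a CSV path.
#' @param out_dir Output directory (created on run).
#' @param seasons Season labels; one simulation is run per label.
#' @param schedule A [build_release_schedule()].
#' @param config A [simulation_config()]; its `rng_seed` is ignored in
#'   favour of `seed`.
#' @param seed Integer master seed for the whole run.
#' @param spat_rho If the site table has no `spat` column, synthetic spat
#'   counts are generated at this target correlation from the first
#'   season's site counts ([simulate_spat_counts()]); `NULL` requires
#'   observed counts.
#' @param verbose 0 (quiet), 1 (per-season progress), 2 (adds per-day
#'   active/exited audit lines).
#' @return A `run_config` object.
#' @export
run_config <- function(field, seeds, sites, out_dir,
                       seasons = c("season1", "season2", "season3"),
                       schedule = build_release_schedule(10, 2000),
                       config = simulation_config(),
                       seed = 1, spat_rho = 0.45, verbose = 1) {
  check_input <- function(x, what, loader) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        abort(sprintf("%s file does not exist: %s", what, x),
          class = "pearldrift_validation_error")
      }
    }
    x
  }
  if (is.list(field) && !inherits(field, "current_field")) {
    if (length(field) != length(seasons)) {
      abort("When `field` is a list it needs one entry per season.",
        class = "pearldrift_validation_error")
    }
    lapply(field, function(f) stopifnot(inherits(f, "current_field")))
  } else {
    check_input(field, "Current field", read_current_field)
  }
  check_input(seeds, "Seed polygon", read_seed_polygons)
  check_input(sites, "Collector site", read_collector_sites)
  if (is.data.frame(sites)) {
    if (!all(c("name", "lon", "lat") %in% names(sites))) {
      abort("Site table must have columns name, lon, lat.",
        class = "pearldrift_validation_error")
    }
    if (!"spat" %in% names(sites) && is.null(spat_rho)) {
      abort("Site table has no `spat` column and no `spat_rho` was given.",
        class = "pearldrift_validation_error")
    }
  }
  structure(
    list(field = field, seeds = seeds, sites = sites, out_dir = out_dir,
         seasons = seasons, schedule = schedule, config = config,
         seed = seed, spat_rho = spat_rho, verbose = verbose),
    class = "run_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "pearldrift_stage_error", parent = e)
  })
}

#' Run the full dispersal-analysis pipeline
#'
#' Executes, per season: a season simulation ([run_season_simulation()]),
#' the four standard visit grids ([window_counts()]), and per-site counts;
#' then, across seasons: synthetic or observed spat comparison
#' (correlation per season on day-60 cumulative counts vs arcsinh spat,
#' combined rank-sum test, per-site one-sample t-tests, normality and
#' variance checks) and the pairwise corridor density matrix from the
#' early/late grids of every season. All outputs are CSV/JSON under
#' `out_dir`, and a manifest listing every output file with its MD5
#' checksum is written last. Identical seeds give byte-identical numeric
#' outputs.
#'
#' @param rc A [run_config()].
#' @return The manifest tibble (`file`, `bytes`, `md5`), invisibly, with
#'   the computed statistics attached as attribute `"stats"`.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  say <- function(lvl, fmt, ...) if (rc$verbose >= lvl) message(sprintf(fmt, ...))

  inputs <- with_stage("load-inputs", {
    fields <- rc$field
    if (is.character(fields)) fields <- read_current_field(fields)
    if (inherits(fields, "current_field")) {
      fields <- stats::setNames(rep(list(fields), length(rc$seasons)), rc$seasons)
    }
    seeds <- if (is.character(rc$seeds)) read_seed_polygons(rc$seeds) else rc$seeds
    sites <- if (is.character(rc$sites)) read_collector_sites(rc$sites) else rc$sites
    list(fields = fields, seeds = seeds, sites = sites)
  })
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, path) {
    readr::write_csv(df, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  season_counts <- list()  # per-season site counts (cumulative60)
  ew_grids <- list()       # early/late grids across seasons
  for (i in seq_along(rc$seasons)) {
    sl <- rc$seasons[i]
    field <- inputs$fields[[i]]
    cfg <- rc$config
    cfg$rng_seed <- rc$seed * 1009L + i
    sdir <- file.path(rc$out_dir, sl)
    dir.create(sdir, showWarnings = FALSE)
    say(1, "[%s] simulating %d particles x %d days ...", sl,
        rc$schedule$total, cfg$duration_days)
    traj <- with_stage(paste0("simulate-", sl),
      run_season_simulation(field, inputs$seeds, rc$schedule, cfg,
                            verbose = rc$verbose >= 2))
    emit(tibble::as_tibble(traj)[, c("day", "particle_id", "lon", "lat", "age", "status")],
         file.path(sdir, "trajectory.csv"))
    # early/late thirds of the recruitment window, the full window, and the
    # cumulative grid to the end of the run (30-40, 50-60, 30-60, 0-60 under
    # the default 60-day protocol)
    rw <- cfg$recruitment_window
    third <- (rw[2] - rw[1]) / 3
    cum_label <- sprintf("cumulative%g", cfg$duration_days)
    windows <- stats::setNames(
      list(c(rw[1], rw[1] + third), c(rw[2] - third, rw[2]), rw,
           c(0, cfg$duration_days)),
      c("early", "late", "full", cum_label)
    )
    grids <- with_stage(paste0("grid-", sl), window_counts(traj, field, windows))
    for (w in names(grids)) {
      emit(as_tibble(grids[[w]]), file.path(sdir, sprintf("grid_%s.csv", w)))
    }
    sc <- with_stage(paste0("site-counts-", sl),
                     site_counts_table(grids, inputs$sites))
    emit(sc, file.path(sdir, "site_counts.csv"))
    season_counts[[sl]] <- sc |>
      dplyr::filter(.data$window == cum_label) |>
      dplyr::transmute(name = .data$name, season = sl, count = .data$count)
    ew_grids <- c(ew_grids, grids[c("early", "late")])
  }

  stats_out <- with_stage("stats", {
    sites <- inputs$sites
    counts_long <- dplyr::bind_rows(season_counts)
    if (!"spat" %in% names(sites)) {
      first <- season_counts[[1]]
      sites$spat <- simulate_spat_counts(
        first$count[match(sites$name, first$name)],
        rho = rc$spat_rho, seed = rc$seed * 2003L + 17L
      )
      emit(sites, file.path(rc$out_dir, "sites_with_synthetic_spat.csv"))
    }
    spat_t <- arcsinh_transform(sites$spat)
    correlations <- purrr::imap_dfr(season_counts, function(sc, sl) {
      cr <- pearson_with_df(sc$count[match(sites$name, sc$name)], spat_t)
      dplyr::mutate(tidy(cr), season = sl, .before = 1)
    })
    rs <- rank_sum_test(counts_long$count, sites$spat)
    tt <- per_site_t_tests(counts_long, sites[, c("name", "spat")])
    norm <- normality_and_variance_checks(c(
      list(arcsinh_spat = spat_t),
      stats::setNames(lapply(season_counts, function(sc) sc$count), names(season_counts))
    ))
    pm <- pairwise_corridor_density(ew_grids, sites)
    list(correlations = correlations, rank_sum = rs, t_tests = tt,
         normality = norm, pairwise = pm, sites = sites)
  })

  with_stage("write-stats", {
    emit(stats_out$correlations, file.path(rc$out_dir, "correlations.csv"))
    emit(tibble::tibble(W = stats_out$rank_sum$statistic, p = stats_out$rank_sum$p_value,
                        m = stats_out$rank_sum$m, n = stats_out$rank_sum$n),
         file.path(rc$out_dir, "rank_sum.csv"))
    emit(stats_out$t_tests, file.path(rc$out_dir, "per_site_t_tests.csv"))
    emit(stats_out$normality$shapiro, file.path(rc$out_dir, "shapiro.csv"))
    lev <- stats_out$normality$levene
    emit(tibble::tibble(statistic = lev$statistic, df1 = lev$df1, df2 = lev$df2, p = lev$p),
         file.path(rc$out_dir, "levene.csv"))
    pm_df <- tibble::as_tibble(unclass(stats_out$pairwise), rownames = "site")
    emit(pm_df, file.path(rc$out_dir, "pairwise_density_matrix.csv"))
    report <- c(
      "Dispersal vs spat recruitment report",
      "====================================",
      sprintf("Seasons: %s", paste(rc$seasons, collapse = ", ")),
      sprintf("Release: %d day(s) x %d particles = %d",
              rc$schedule$seed_days, rc$schedule$particles_per_day, rc$schedule$total),
      sprintf("Master seed: %d", rc$seed),
      "",
      "Per-season Pearson correlation (site visit counts vs arcsinh spat):",
      sprintf("  %s: r(%d) = %.3f, p = %.3g, R^2 = %.4f",
              stats_out$correlations$season, stats_out$correlations$parameter,
              stats_out$correlations$estimate, stats_out$correlations$p.value,
              stats_out$correlations$r.squared),
      "",
      sprintf("Wilcoxon rank sum (seasons pooled vs spat): W = %g, p = %.3g",
              stats_out$rank_sum$statistic, stats_out$rank_sum$p_value),
      sprintf("Per-site t-tests: %d of %d sites with p < 0.05 (raw)",
              sum(stats_out$t_tests$p < 0.05, na.rm = TRUE), nrow(stats_out$t_tests))
    )
    writeLines(report, file.path(rc$out_dir, "report.txt"))
    outputs <- c(outputs, file.path(rc$out_dir, "report.txt"))
  })

  manifest <- with_stage("manifest", {
    m <- tibble::tibble(
      file = sub(paste0("^", rc$out_dir, "/?"), "", outputs),
      bytes = file.size(outputs),
      md5 = unname(tools::md5sum(outputs))
    )
    meta <- list(
      package = "pearldrift",
      version = as.character(utils::packageVersion("pearldrift")),
      seed = rc$seed,
      seasons = rc$seasons,
      schedule = list(seed_days = rc$schedule$seed_days,
                      particles_per_day = rc$schedule$particles_per_day),
      Eh = rc$config$Eh, duration_days = rc$config$duration_days,
      files = m
    )
    jsonlite::write_json(meta, file.path(rc$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(m, file.path(rc$out_dir, "manifest.csv"), progress = FALSE)
    m
  })
  say(1, "Pipeline complete: %d output files in %s", nrow(manifest), rc$out_dir)
  attr(manifest, "stats") <- stats_out
  invisible(manifest)
}
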