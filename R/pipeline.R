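## End-to-end orchestration: currents -> reefs -> seeding -> tracking ->
## events -> matrices/tables, written to a run directory with a manifest.
## All defaults mirror the reference biophysical parameterisation (30-min
## RK2 step, K = 933 m^2/s, 10-day PLD with 4-day precompetency, releases
## every 2 days through February-March at midnight, 200 larvae/km^2 above
## 1 km^2 with a 200-larvae floor).

## rolling polynomial hash (config fingerprinting only, not cryptographic)
config_hash <- function(txt) {
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory for run artefacts.
#' @param currents_path optional NetCDF currents file; if NULL a synthetic
#'   scenario field is generated per release year.
#' @param reefs_path optional GeoJSON reef file; if NULL a synthetic reef
#'   set is generated.
#' @param scenario synthetic flow scenario name ("A", "B" or "C").
#' @param grid_resolution node spacing for generated fields, degrees.
#' @param years release years.
#' @param months spawning months.
#' @param interval_days release spacing, days.
#' @param tracker a \code{\link{tracker_config}}.
#' @param biology a \code{\link{biology_config}}.
#' @param density,floor_count,threshold_km2 seeding rule constants.
#' @param n_per_complex,complexes,band_lats synthetic reef layout (used only
#'   when \code{reefs_path} is NULL).
#' @param coast synthetic coastline (used when generating currents/reefs).
#' @param destination_complex complex for the temporal contribution table.
#' @param seed master seed; every random stage derives from it.
#' @param write_trajectories also write trajectories.nc (can be large)?
#' @return object of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       currents_path = NULL, reefs_path = NULL,
                       scenario = "A", grid_resolution = 1 / 24,
                       years = 1994:2014, months = 2:3, interval_days = 2,
                       tracker = tracker_config(), biology = biology_config(),
                       density = 200, floor_count = 200, threshold_km2 = 1,
                       n_per_complex = 3,
                       complexes = names(default_band_lats()),
                       band_lats = unname(default_band_lats()),
                       coast = bight_coast(),
                       destination_complex = "MRC",
                       seed = 1, write_trajectories = FALSE) {
  stop_if_not(density > 0 && floor_count > 0 && threshold_km2 > 0,
              "run_config: seeding constants must be positive")
  for (p in c(currents_path, reefs_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("run_config: input file does not exist: ", p)
    }
  }
  structure(list(out_dir = out_dir, currents_path = currents_path,
                 reefs_path = reefs_path, scenario = scenario,
                 grid_resolution = grid_resolution,
                 years = years, months = months,
                 interval_days = interval_days,
                 tracker = tracker, biology = biology,
                 density = density, floor_count = floor_count,
                 threshold_km2 = threshold_km2,
                 n_per_complex = n_per_complex, complexes = complexes,
                 band_lats = band_lats, coast = coast,
                 destination_complex = destination_complex,
                 seed = as.integer(seed),
                 write_trajectories = write_trajectories),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys override the built-in defaults, so an empty file reproduces the
#' reference parameterisation. Recognised keys: out_dir, currents, reefs,
#' scenario, grid_resolution, years, months, interval_days, dt, diffusivity,
#' max_age_days, pld_days, precompetency_days, density, floor_count,
#' threshold_km2, n_per_complex, destination_complex, seed,
#' write_trajectories.
#'
#' @param path YAML file.
#' @param out_dir output directory (overrides any out_dir key).
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path) %||% list()
  trk <- tracker_config(dt = y$dt %||% 1800,
                        diffusivity = y$diffusivity %||% 933,
                        max_age_days = y$max_age_days %||% 10,
                        seed = y$seed %||% 1)
  bio <- biology_config(pld_days = y$pld_days %||% 10,
                        precompetency_days = y$precompetency_days %||% 4)
  run_config(out_dir = out_dir %||% y$out_dir %||% stop(
               "read_run_config: out_dir required"),
             currents_path = y$currents, reefs_path = y$reefs,
             scenario = y$scenario %||% "A",
             grid_resolution = y$grid_resolution %||% (1 / 24),
             years = y$years %||% 1994:2014,
             months = y$months %||% 2:3,
             interval_days = y$interval_days %||% 2,
             tracker = trk, biology = bio,
             density = y$density %||% 200,
             floor_count = y$floor_count %||% 200,
             threshold_km2 = y$threshold_km2 %||% 1,
             n_per_complex = y$n_per_complex %||% 3,
             destination_complex = y$destination_complex %||% "MRC",
             seed = y$seed %||% 1,
             write_trajectories = isTRUE(y$write_trajectories))
}

stage <- function(name, expr) {
  message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
}

#' Run the dispersal pipeline
#'
#' Orchestrates currents -> reefs -> seeding -> tracking -> event detection
#' -> aggregation, writing events.csv, reef- and complex-level connectivity
#' matrices, travel-time mean/sd matrices, the temporal contribution table
#' and a machine-readable manifest into the output directory. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{dispersal_run} (invisibly contains all
#'   in-memory products and the output directory).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stop_if_not(dir.exists(cfg$out_dir), "run_pipeline: cannot create out_dir")

  reefs <- stage("reefs", {
    if (!is.null(cfg$reefs_path)) read_reefs(cfg$reefs_path)
    else generate_reefs(cfg$coast, cfg$n_per_complex, cfg$complexes,
                        cfg$band_lats, seed = cfg$seed + 1)
  })
  counts <- seed_count(reefs$areas_km2, cfg$density, cfg$floor_count,
                       cfg$threshold_km2)
  names(counts) <- reefs$reef_ids

  schedule <- stage("schedule",
                    build_release_schedule(cfg$years, cfg$interval_days,
                                           cfg$months))
  shared_field <- if (!is.null(cfg$currents_path)) {
    stage("currents", read_currents(cfg$currents_path))
  } else NULL

  all_events <- list()
  status_tally <- stats::setNames(rep(0L, 4), STATUS_LEVELS)
  released_total <- stats::setNames(rep(0L, length(counts)), names(counts))
  trajectories_path <- if (cfg$write_trajectories)
    file.path(cfg$out_dir, "trajectories.nc") else NULL

  with_seed(cfg$seed, {
    for (yi in seq_along(cfg$years)) {
      year <- cfg$years[yi]
      field <- if (!is.null(shared_field)) shared_field else
        stage(sprintf("currents %d", year), {
          first <- as_utc(sprintf("%04d-%02d-01", year, cfg$months[1]))
          last <- max(schedule[format(schedule, "%Y") == sprintf("%04d", year)])
          times <- seq(first, last + (cfg$tracker$max_age_days + 1) * 86400,
                       by = 86400)
          g <- default_grid(first, length(times), cfg$grid_resolution)
          velocity_field(scenario_library(cfg$scenario, g$times, cfg$coast), g)
        })
      rel_days <- schedule[format(schedule, "%Y") == sprintf("%04d", year)]
      releases <- lapply(rel_days, function(day) {
        pts <- lapply(seq_along(reefs$polygons), function(k) {
          p <- sample_release_points(reefs$polygons[[k]], counts[k])
          cbind(p, source_reef = reefs$reef_ids[k])
        })
        pts <- do.call(rbind, pts)
        list(lon = pts$lon, lat = pts$lat, source_reef = pts$source_reef,
             release_time = day,
             particle_id = sprintf("%s_%05d", format(day, "%Y%m%d"),
                                   seq_len(nrow(pts))))
      })
      trk <- cfg$tracker
      trk$seed <- (cfg$seed * 1009L + yi) %% .Machine$integer.max
      traj <- stage(sprintf("tracking %d", year),
                    run_tracker(field, releases, trk))
      for (b in traj$batches) {
        fin <- b$status[, ncol(b$status)]
        status_tally <- status_tally +
          tabulate(fin + 1L, nbins = 4)
        released_total <- released_total +
          tabulate(factor(b$source_reef, names(counts)),
                   nbins = length(counts))
      }
      message(sprintf("  year %d: %d particles, final status %s", year,
                      n_particles(traj),
                      paste(STATUS_LEVELS, status_tally, sep = "=",
                            collapse = " ")))
      if (!is.null(trajectories_path) && yi == 1) {
        write_trajectories(traj, trajectories_path)
      }
      all_events[[yi]] <- stage(sprintf("events %d", year),
                                detect_events(traj, reefs, cfg$biology))
    }
  })
  events <- do.call(rbind, all_events)

  mat <- stage("matrix", build_matrix(events, reefs, released_total))
  tts <- stage("travel times", travel_time_stats(events, reefs))
  cmat <- stage("complex aggregation", aggregate_complexes(mat))
  temporal <- stage("temporal contributions",
                    temporal_contributions(events, cfg$destination_complex,
                                           complex_map(reefs), "year"))

  stage("artefacts", {
    ev_out <- events
    ev_out$release_time <- format(ev_out$release_time, "%Y-%m-%dT%H:%M:%SZ")
    ev_out$arrival_time <- format(ev_out$arrival_time, "%Y-%m-%dT%H:%M:%SZ")
    utils::write.csv(ev_out, file.path(cfg$out_dir, "events.csv"),
                     row.names = FALSE)
    write_matrix_tsv(mat$counts,
                     file.path(cfg$out_dir, "connectivity_reefs.tsv"))
    write_matrix_tsv(cmat$counts,
                     file.path(cfg$out_dir, "connectivity_complexes.tsv"))
    write_matrix_tsv(tts$mean_h,
                     file.path(cfg$out_dir, "travel_time_mean_h.tsv"))
    write_matrix_tsv(tts$sd_h,
                     file.path(cfg$out_dir, "travel_time_sd_h.tsv"))
    utils::write.csv(temporal,
                     file.path(cfg$out_dir, "temporal_contributions.csv"),
                     row.names = FALSE)
    write_reefs(reefs, file.path(cfg$out_dir, "reefs.geojson"))
    cfg_txt <- yaml::as.yaml(unclass_recursive(cfg))
    manifest <- list(
      package = "reefdrift",
      version = as.character(utils::packageVersion("reefdrift")),
      r_version = as.character(getRversion()),
      seed = cfg$seed,
      config_hash = config_hash(cfg_txt),
      config = yaml::yaml.load(cfg_txt),
      particles_released = sum(released_total),
      events = nrow(events),
      final_status = as.list(status_tally))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  structure(list(config = cfg, reefs = reefs, released = released_total,
                 events = events, matrix = mat, travel_times = tts,
                 complex_matrix = cmat, temporal = temporal,
                 status_tally = status_tally, out_dir = cfg$out_dir),
            class = "dispersal_run")
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x <- lapply(x, unclass_recursive)
  } else if (inherits(x, "POSIXct")) {
    x <- format(x, "%Y-%m-%dT%H:%M:%SZ")
  }
  x
}

#' @export
print.dispersal_run <- function(x, ...) {
  cat(sprintf("dispersal_run: %d larvae released, %d connectivity events, %d reefs\n",
              sum(x$released), nrow(x$events), length(x$reefs$reef_ids)))
  cat("artefacts in ", x$out_dir, "\n", sep = "")
  invisible(x)
}

#' Summarise a pipeline run
#'
#' Accepts either a \code{dispersal_run} object or a run directory produced
#' by \code{\link{run_pipeline}} and computes complex-level totals,
#' self-recruitment fractions and within- vs between-complex mean travel
#' times. The report is stable across re-reads of the same run directory.
#'
#' @param x a \code{dispersal_run} or path to a run directory.
#' @return object of class \code{dispersal_report}.
#' @export
summarize_run <- function(x) {
  if (inherits(x, "dispersal_run")) {
    cmat <- x$complex_matrix$counts
    reef_counts <- x$matrix$counts
    released <- x$complex_matrix$released
    tt <- x$travel_times
    cx <- x$matrix$complex_ids
  } else {
    stop_if_not(dir.exists(x), "summarize_run: no such run directory")
    need <- c("connectivity_reefs.tsv", "connectivity_complexes.tsv",
              "travel_time_mean_h.tsv", "manifest.json", "reefs.geojson")
    miss <- need[!file.exists(file.path(x, need))]
    if (length(miss) > 0) {
      stop("summarize_run: incomplete run directory, missing: ",
           paste(miss, collapse = ", "))
    }
    reef_counts <- as.matrix(utils::read.delim(
      file.path(x, "connectivity_reefs.tsv"), row.names = 1,
      check.names = FALSE))
    cmat <- as.matrix(utils::read.delim(
      file.path(x, "connectivity_complexes.tsv"), row.names = 1,
      check.names = FALSE))
    ttm <- as.matrix(utils::read.delim(
      file.path(x, "travel_time_mean_h.tsv"), row.names = 1,
      check.names = FALSE))
    tt <- list(mean_h = ttm, n = !is.na(ttm) * 1L)
    reefs <- read_reefs(file.path(x, "reefs.geojson"))
    cx <- reefs$complex_ids
    released <- NULL
  }
  same <- outer(cx, cx, "==")
  connected <- !is.na(tt$mean_h)
  rep_obj <- list(
    total_events = sum(reef_counts),
    complex_totals = cmat,
    complex_released = released,
    self_recruitment = sum(diag(reef_counts)),
    self_recruitment_fraction =
      if (sum(reef_counts) > 0) sum(diag(reef_counts)) / sum(reef_counts)
      else NA_real_,
    within_complex_mean_h =
      if (any(connected & same)) mean(tt$mean_h[connected & same]) else NA_real_,
    between_complex_mean_h =
      if (any(connected & !same)) mean(tt$mean_h[connected & !same]) else NA_real_)
  structure(rep_obj, class = "dispersal_report")
}

#' @export
print.dispersal_report <- function(x, ...) {
  if (x$total_events == 0) {
    cat("dispersal_report: no connectivity events observed\n")
    return(invisible(x))
  }
  cat("dispersal_report\n")
  cat(sprintf("  total connectivity events: %d\n", x$total_events))
  cat(sprintf("  self-recruitment: %d events (%.1f%%)\n",
              x$self_recruitment, 100 * x$self_recruitment_fraction))
  fmt_h <- function(v) if (is.na(v)) "n/a (no connections)" else
    sprintf("%.1f h", v)
  cat(sprintf("  mean travel time within complexes:  %s\n",
              fmt_h(x$within_complex_mean_h)))
  cat(sprintf("  mean travel time between complexes: %s\n",
              fmt_h(x$between_complex_mean_h)))
  cat("  complex-level totals (source rows, destination columns):\n")
  print(x$complex_totals)
  invisible(x)
}
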