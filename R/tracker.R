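## Particle status machine: ACTIVE <-> STRANDED are the mobile states;
## INACTIVE (aged out) and LEFT_DOMAIN are absorbing. Stranded larvae keep
## their last ocean position, keep ageing, and re-enter the ocean if the
## flow later permits.

#' @export
STATUS_LEVELS <- c("ACTIVE", "STRANDED", "INACTIVE", "LEFT_DOMAIN")
ST_ACTIVE <- 0L; ST_STRANDED <- 1L; ST_INACTIVE <- 2L; ST_LEFT <- 3L

#' Tracker configuration
#'
#' @param dt internal time step, seconds (default 1800 = 30 min).
#' @param diffusivity horizontal random-walk diffusivity K, m^2/s
#'   (default 933; per-axis displacement std is sqrt(2 K dt)).
#' @param max_age_days tracking span per larva, days (default 10, the
#'   pelagic larval duration).
#' @param seed master RNG seed for the random walk.
#' @return object of class \code{tracker_config}.
#' @export
tracker_config <- function(dt = 1800, diffusivity = 933, max_age_days = 10,
                           seed = 1) {
  dt <- as.numeric(dt)
  diffusivity <- as.numeric(diffusivity)
  max_age_days <- as.numeric(max_age_days)
  stop_if_not(dt > 0, "tracker_config: dt must be > 0")
  stop_if_not(diffusivity >= 0, "tracker_config: diffusivity must be >= 0")
  stop_if_not(max_age_days > 0, "tracker_config: max_age_days must be > 0")
  structure(list(dt = dt, diffusivity = diffusivity,
                 max_age_days = max_age_days, seed = as.integer(seed)),
            class = "tracker_config")
}

#' One explicit-midpoint (RK2) advection step
#'
#' Half step with the velocity at the current position and time, full step
#' with the velocity at the midpoint and \code{t + dt/2}; displacements are
#' computed in local metres and converted to degrees at the midpoint
#' latitude. Positions where velocity cannot be sampled (outside the domain
#' hull or time span) come back \code{NA}.
#'
#' @param field \code{\link{flow_field}} or sampler function.
#' @param lon,lat positions, degrees (vectorised).
#' @param t time (POSIXct or numeric seconds).
#' @param dt step, seconds.
#' @return list(lon, lat) of tentative positions.
#' @export
rk2_step <- function(field, lon, lat, t, dt) {
  t <- as.numeric(t)
  v1 <- sample_velocity(field, lon, lat, t)
  d1 <- meters_to_degrees(v1$u * dt / 2, v1$v * dt / 2, lat)
  mlon <- lon + d1$dlon; mlat <- lat + d1$dlat
  v2 <- sample_velocity(field, mlon, mlat, t + dt / 2)
  d2 <- meters_to_degrees(v2$u * dt, v2$v * dt,
                          ifelse(is.na(mlat), lat, mlat))
  list(lon = lon + d2$dlon, lat = lat + d2$dlat)
}

#' Random-walk displacement increments
#'
#' Independent Gaussian increments per axis with standard deviation
#' \code{sqrt(2 K dt)} metres (Fickian diffusivity), drawn from the current
#' RNG stream.
#'
#' @param K diffusivity, m^2/s (>= 0).
#' @param dt step, seconds.
#' @param n number of particles.
#' @return list(dx_m, dy_m).
#' @export
diffusion_step <- function(K, dt, n = 1) {
  stop_if_not(K >= 0, "diffusion_step: K must be >= 0")
  if (K == 0) return(list(dx_m = numeric(n), dy_m = numeric(n)))
  s <- sqrt(2 * K * dt)
  list(dx_m = stats::rnorm(n, 0, s), dy_m = stats::rnorm(n, 0, s))
}

#' Advance the particle ensemble by one step
#'
#' Mobile (ACTIVE or STRANDED) particles take an RK2 advection step plus a
#' diffusion displacement. A tentative position in ocean is accepted
#' (ACTIVE); on land the particle keeps its previous position and strands;
#' outside the grid hull it freezes as LEFT_DOMAIN. Ages advance for mobile
#' particles; a particle older than the maximum age freezes as INACTIVE.
#' Random draws are made for the full ensemble every step so trajectories do
#' not depend on the statuses of other particles.
#'
#' @param field \code{\link{flow_field}}.
#' @param particles list with vectors lon, lat, status, age_sec.
#' @param t current time (numeric seconds or POSIXct).
#' @param cfg a \code{\link{tracker_config}}.
#' @return updated particles list.
#' @export
advance <- function(field, particles, t, cfg) {
  n <- length(particles$lon)
  dif <- diffusion_step(cfg$diffusivity, cfg$dt, n)
  mob <- particles$status %in% c(ST_ACTIVE, ST_STRANDED)
  if (any(mob)) {
    lon0 <- particles$lon[mob]; lat0 <- particles$lat[mob]
    adv <- rk2_step(field, lon0, lat0, t, cfg$dt)
    dd <- meters_to_degrees(dif$dx_m[mob], dif$dy_m[mob], lat0)
    tlon <- adv$lon + dd$dlon; tlat <- adv$lat + dd$dlat
    failed <- is.na(tlon) | is.na(tlat)
    code <- rep(2L, length(tlon))
    ok <- !failed
    code[ok] <- ocean_code(field, tlon[ok], tlat[ok])
    idx <- which(mob)
    move <- code == 0L
    particles$lon[idx[move]] <- tlon[move]
    particles$lat[idx[move]] <- tlat[move]
    particles$status[idx[move]] <- ST_ACTIVE
    particles$status[idx[code == 1L]] <- ST_STRANDED   # held at last ocean pos
    particles$status[idx[code == 2L]] <- ST_LEFT
    particles$age_sec[idx] <- particles$age_sec[idx] + cfg$dt
    aged <- mob & particles$age_sec > cfg$max_age_days * 86400
    particles$status[aged & particles$status %in% c(ST_ACTIVE, ST_STRANDED)] <-
      ST_INACTIVE
  }
  particles
}

#' Track released particle batches through a flow field
#'
#' Each batch is stepped at the tracker resolution from its release until
#' release + maximum age, recording position and status at every step.
#' Particles are never removed, only re-flagged. The run is deterministic
#' for a fixed configuration seed.
#'
#' @param field a \code{\link{flow_field}}.
#' @param releases list of release batches; each a list with vectors
#'   \code{lon}, \code{lat}, optional \code{source_reef} and
#'   \code{particle_id}, and scalar \code{release_time} (POSIXct).
#' @param cfg a \code{\link{tracker_config}}.
#' @return object of class \code{trajectory_set}.
#' @export
run_tracker <- function(field, releases, cfg = tracker_config()) {
  stop_if_not(length(releases) >= 1, "run_tracker: empty release list")
  t_end_field <- as.numeric(max(field$grid$times))
  with_seed(cfg$seed, {
    batches <- vector("list", length(releases))
    for (b in seq_along(releases)) {
      rel <- releases[[b]]
      n <- length(rel$lon)
      t0 <- as.numeric(as_utc(rel$release_time))
      n_steps <- round(cfg$max_age_days * 86400 / cfg$dt)
      if (t0 + n_steps * cfg$dt > t_end_field) {
        n_steps <- max(0, floor((t_end_field - t0) / cfg$dt))
        warning("run_tracker: field ends before release + max age; ",
                "batch ", b, " truncated to ", n_steps, " steps")
      }
      lon <- matrix(NA_real_, n, n_steps + 1)
      lat <- matrix(NA_real_, n, n_steps + 1)
      status <- matrix(NA_integer_, n, n_steps + 1)
      p <- list(lon = rel$lon, lat = rel$lat,
                status = rep(ST_ACTIVE, n), age_sec = rep(0, n))
      ## a release point on land counts as stranded from the start
      p$status[ocean_code(field, p$lon, p$lat) == 1L] <- ST_STRANDED
      p$status[ocean_code(field, p$lon, p$lat) == 2L] <- ST_LEFT
      lon[, 1] <- p$lon; lat[, 1] <- p$lat; status[, 1] <- p$status
      t <- t0
      for (s in seq_len(n_steps)) {
        p <- advance(field, p, t, cfg)
        t <- t0 + s * cfg$dt
        lon[, s + 1] <- p$lon; lat[, s + 1] <- p$lat
        status[, s + 1] <- p$status
      }
      batches[[b]] <- list(
        release_time = as_utc(rel$release_time),
        times = t0 + cfg$dt * (0:n_steps),
        lon = lon, lat = lat, status = status,
        particle_id = rel$particle_id %||% sprintf("b%d_p%d", b, seq_len(n)),
        source_reef = rel$source_reef %||% rep(NA_character_, n))
    }
    structure(list(batches = batches, config = cfg),
              class = "trajectory_set")
  })
}

n_particles <- function(traj) {
  sum(vapply(traj$batches, function(b) nrow(b$lon), integer(1)))
}

#' @export
print.trajectory_set <- function(x, ...) {
  final <- unlist(lapply(x$batches, function(b) b$status[, ncol(b$status)]))
  tab <- table(factor(STATUS_LEVELS[final + 1], levels = STATUS_LEVELS))
  cat(sprintf("trajectory_set: %d particles in %d release batches; final status: %s\n",
              n_particles(x), length(x$batches),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  out <- lapply(x$batches, function(b) {
    n <- nrow(b$lon); Tn <- ncol(b$lon)
    data.frame(
      particle_id = rep(b$particle_id, Tn),
      source_reef = rep(b$source_reef, Tn),
      time = as_utc(as.POSIXct(rep(b$times, each = n), origin = "1970-01-01",
                               tz = "UTC")),
      lon = as.vector(b$lon), lat = as.vector(b$lat),
      status = STATUS_LEVELS[as.vector(b$status) + 1])
  })
  do.call(rbind, out)
}

#' @export
plot.trajectory_set <- function(x, max_particles = 200, col = "#00000040", ...) {
  df <- as.data.frame(x)
  ids <- unique(df$particle_id)
  if (length(ids) > max_particles) ids <- ids[seq_len(max_particles)]
  df <- df[df$particle_id %in% ids, ]
  graphics::plot(NA, xlim = range(df$lon, na.rm = TRUE),
                 ylim = range(df$lat, na.rm = TRUE),
                 xlab = "longitude", ylab = "latitude", ...)
  for (id in ids) {
    d <- df[df$particle_id == id, ]
    graphics::lines(d$lon, d$lat, col = col)
  }
  invisible(x)
}

#' Write trajectories as CF-style NetCDF (trajectory x obs)
#'
#' @param traj a \code{trajectory_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  nmax <- max(vapply(traj$batches, function(b) ncol(b$lon), integer(1)))
  ntr <- n_particles(traj)
  dtr <- ncdf4::ncdim_def("trajectory", "", seq_len(ntr),
                          create_dimvar = FALSE)
  dob <- ncdf4::ncdim_def("obs", "", seq_len(nmax), create_dimvar = FALSE)
  miss <- 1e36
  vlon <- ncdf4::ncvar_def("lon", "degrees_east", list(dob, dtr), miss,
                           prec = "double")
  vlat <- ncdf4::ncvar_def("lat", "degrees_north", list(dob, dtr), miss,
                           prec = "double")
  vtim <- ncdf4::ncvar_def("time", "seconds since 1970-01-01 00:00:00",
                           list(dob, dtr), miss, prec = "double")
  vst <- ncdf4::ncvar_def("status", "1", list(dob, dtr), -1L, prec = "integer")
  nc <- ncdf4::nc_create(path, list(vlon, vlat, vtim, vst))
  on.exit(ncdf4::nc_close(nc))
  row0 <- 0
  for (b in traj$batches) {
    n <- nrow(b$lon); Tn <- ncol(b$lon)
    pad <- function(m, fill) {
      out <- matrix(fill, nmax, n)
      out[seq_len(Tn), ] <- t(m)
      out
    }
    start <- c(1, row0 + 1); count <- c(nmax, n)
    ncdf4::ncvar_put(nc, vlon, pad(ifelse(is.na(b$lon), miss, b$lon), miss),
                     start = start, count = count)
    ncdf4::ncvar_put(nc, vlat, pad(ifelse(is.na(b$lat), miss, b$lat), miss),
                     start = start, count = count)
    ncdf4::ncvar_put(nc, vtim,
                     pad(matrix(b$times, n, Tn, byrow = TRUE), miss),
                     start = start, count = count)
    ncdf4::ncvar_put(nc, vst, pad(b$status, -1L), start = start, count = count)
    row0 <- row0 + n
  }
  ncdf4::ncatt_put(nc, 0, "featureType", "trajectory")
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  ncdf4::ncatt_put(nc, "status", "flag_values", "0 1 2 3")
  ncdf4::ncatt_put(nc, "status", "flag_meanings",
                   "active stranded inactive left_domain")
  invisible(path)
}
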