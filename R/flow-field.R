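#' Gridded surface current field
#'
#' Container for a time series of surface velocity snapshots on a regular
#' lon/lat grid with a static landmask. Arrays are stored \code{[lon, lat,
#' time]}; velocities are m/s and are \code{NA} exactly on land nodes.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param u,v numeric arrays \code{[lon, lat, time]}, m/s.
#' @param landmask logical matrix \code{[lon, lat]}, \code{TRUE} = land.
#' @return object of class \code{flow_field}.
#' @export
flow_field <- function(grid, u, v, landmask) {
  nd <- c(length(grid$lon), length(grid$lat), length(grid$times))
  stop_if_not(identical(dim(u), nd) && identical(dim(v), nd),
              "flow_field: u/v dimensions must match grid [lon, lat, time]")
  stop_if_not(identical(dim(landmask), nd[1:2]),
              "flow_field: landmask dimensions must match grid [lon, lat]")
  ocean <- !landmask
  for (k in seq_len(nd[3])) {
    if (!all(is.finite(u[, , k][ocean])) || !all(is.finite(v[, , k][ocean]))) {
      stop("flow_field: non-finite velocity at ocean nodes (time index ", k, ")")
    }
  }
  structure(list(grid = grid, u = u, v = v, landmask = landmask),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  g <- x$grid
  sp <- sqrt(x$u^2 + x$v^2)
  cat(sprintf(paste0("flow_field: %d x %d nodes x %d times, ",
                     "%.1f%% land, max speed %.3f m/s\n"),
              length(g$lon), length(g$lat), length(g$times),
              100 * mean(x$landmask), max(sp, na.rm = TRUE)))
  invisible(x)
}

#' Generate a gridded velocity field from a scenario
#'
#' Evaluates the scenario streamfunction on the grid nodes at every snapshot
#' time and differentiates it with central differences in a local-metres
#' (spherical) metric: \eqn{u = -\partial\psi/\partial y},
#' \eqn{v\cos\varphi = \partial\psi/\partial x_{eq}}. Because the same
#' discrete operators appear in the spherical divergence, every generated
#' field is non-divergent to machine precision at interior ocean nodes.
#' Land nodes (from the scenario coastline) are masked \code{NA}.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param grid a \code{\link{grid_spec}}.
#' @return a \code{\link{flow_field}}.
#' @export
velocity_field <- function(spec, grid) {
  nlon <- length(grid$lon); nlat <- length(grid$lat); nt <- length(grid$times)
  mask <- make_landmask(grid, spec$coast)
  dy <- grid$dlat * m_per_deg_lat()
  dxeq <- grid$dlon * (EARTH_RADIUS * pi / 180)
  coslat <- cos(grid$lat * pi / 180)
  lonm <- matrix(grid$lon, nlon, nlat)
  latm <- matrix(grid$lat, nlon, nlat, byrow = TRUE)
  u <- array(NA_real_, c(nlon, nlat, nt))
  v <- array(NA_real_, c(nlon, nlat, nt))
  for (k in seq_len(nt)) {
    psi <- matrix(streamfunction(spec, as.vector(lonm), as.vector(latm),
                                 grid$times[k]), nlon, nlat)
    if (!all(is.finite(psi))) stop("velocity_field: non-finite streamfunction")
    uk <- matrix(0, nlon, nlat); vck <- matrix(0, nlon, nlat)
    j <- 2:(nlat - 1)
    uk[, j] <- -(psi[, j + 1] - psi[, j - 1]) / (2 * dy)
    uk[, 1] <- -(psi[, 2] - psi[, 1]) / dy
    uk[, nlat] <- -(psi[, nlat] - psi[, nlat - 1]) / dy
    i <- 2:(nlon - 1)
    vck[i, ] <- (psi[i + 1, ] - psi[i - 1, ]) / (2 * dxeq)
    vck[1, ] <- (psi[2, ] - psi[1, ]) / dxeq
    vck[nlon, ] <- (psi[nlon, ] - psi[nlon - 1, ]) / dxeq
    vk <- sweep(vck, 2, coslat, "/")
    uk[mask] <- NA_real_; vk[mask] <- NA_real_
    u[, , k] <- uk; v[, , k] <- vk
  }
  flow_field(grid, u, v, mask)
}

#' Discrete divergence of a field snapshot
#'
#' Spherical-metric central-difference divergence
#' \eqn{(1/\cos\varphi)\,[\partial u/\partial x_{eq} +
#' \partial(v\cos\varphi)/\partial y]} at interior nodes; \code{NA} on land,
#' at edges, and wherever a stencil node is land. Units 1/s.
#'
#' @param field a \code{\link{flow_field}}.
#' @param time_index snapshot index.
#' @return matrix \code{[lon, lat]}.
#' @export
divergence <- function(field, time_index = 1) {
  g <- field$grid
  nlon <- length(g$lon); nlat <- length(g$lat)
  dy <- g$dlat * m_per_deg_lat()
  dxeq <- g$dlon * (EARTH_RADIUS * pi / 180)
  coslat <- cos(g$lat * pi / 180)
  u <- field$u[, , time_index]
  vc <- sweep(field$v[, , time_index], 2, coslat, "*")
  div <- matrix(NA_real_, nlon, nlat)
  i <- 2:(nlon - 1); j <- 2:(nlat - 1)
  dudx <- (u[i + 1, j] - u[i - 1, j]) / (2 * dxeq)
  dvdy <- (vc[i, j + 1] - vc[i, j - 1]) / (2 * dy)
  div[i, j] <- sweep(dudx + dvdy, 2, coslat[j], "/")
  div
}

#' Write a current field as CF-style NetCDF
#'
#' Dimensions (longitude, latitude, time); double variables \code{uo},
#' \code{vo} in \code{m s-1} with CF standard names, and an integer
#' \code{landmask} (1 = land, 0 = ocean). Reading the file back with
#' \code{\link{read_currents}} reproduces the arrays exactly.
#'
#' @param field a \code{\link{flow_field}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_currents <- function(field, path) {
  g <- field$grid
  dlon <- ncdf4::ncdim_def("longitude", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("latitude", "degrees_north", g$lat)
  dtim <- ncdf4::ncdim_def("time", "seconds since 1970-01-01 00:00:00",
                           as.numeric(g$times), unlim = TRUE)
  miss <- 1e36
  vu <- ncdf4::ncvar_def("uo", "m s-1", list(dlon, dlat, dtim), miss,
                         longname = "eastward surface velocity", prec = "double")
  vv <- ncdf4::ncvar_def("vo", "m s-1", list(dlon, dlat, dtim), miss,
                         longname = "northward surface velocity", prec = "double")
  vm <- ncdf4::ncvar_def("landmask", "1", list(dlon, dlat),
                         longname = "land binary mask", prec = "integer")
  nc <- tryCatch(ncdf4::nc_create(path, list(vu, vv, vm)),
                 error = function(e) stop("write_currents: cannot create ",
                                          path, ": ", conditionMessage(e)))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, ifelse(is.na(field$u), miss, field$u))
  ncdf4::ncvar_put(nc, vv, ifelse(is.na(field$v), miss, field$v))
  ncdf4::ncvar_put(nc, vm, field$landmask * 1L)
  ncdf4::ncatt_put(nc, vu, "standard_name", "eastward_sea_water_velocity")
  ncdf4::ncatt_put(nc, vv, "standard_name", "northward_sea_water_velocity")
  ncdf4::ncatt_put(nc, "longitude", "standard_name", "longitude")
  ncdf4::ncatt_put(nc, "latitude", "standard_name", "latitude")
  ncdf4::ncatt_put(nc, "time", "standard_name", "time")
  ncdf4::ncatt_put(nc, "landmask", "comment", "1 = land, 0 = ocean")
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  invisible(path)
}

## default variable-name dialects accepted by read_currents
default_var_map <- function() {
  list(u = c("uo", "u", "eastward_velocity", "water_u"),
       v = c("vo", "v", "northward_velocity", "water_v"),
       landmask = c("landmask", "land_binary_mask", "mask"))
}

velocity_units_ok <- function(units) {
  gsub("[ .*]", "", tolower(units)) %in%
    c("ms-1", "m/s", "meterssecond-1", "metersecond-1", "ms^-1")
}

parse_time_units <- function(units, vals) {
  m <- regmatches(units, regexec("^(\\w+)s? since (.+)$", units))[[1]]
  if (length(m) == 0) stop("read_currents: unsupported time units: ", units)
  mult <- switch(tolower(m[2]),
                 second = 1, seconds = 1, hour = 3600, hours = 3600,
                 day = 86400, days = 86400,
                 stop("read_currents: unsupported time unit: ", m[2]))
  origin <- as_utc(m[3])
  origin + vals * mult
}

#' Read a CF-style NetCDF current file
#'
#' Tolerant of variable-name dialects via \code{var_map}; latitude stored
#' descending is normalised to ascending with rows reordered; missing-value
#' fills are converted to the landmask (a node is land if the file's mask
#' says so, or if any snapshot is missing there).
#'
#' @param path NetCDF file.
#' @param var_map optional list with character vectors \code{u}, \code{v},
#'   \code{landmask} of candidate variable names, tried in order.
#' @return a \code{\link{flow_field}}.
#' @export
read_currents <- function(path, var_map = NULL) {
  if (!file.exists(path)) stop("read_currents: no such file: ", path)
  vm <- utils::modifyList(default_var_map(), var_map %||% list())
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  pick <- function(cands, what, required = TRUE) {
    hit <- cands[cands %in% names(nc$var)]
    if (length(hit) == 0) {
      if (required) stop("read_currents: no ", what, " variable found (tried: ",
                         paste(cands, collapse = ", "), ")")
      return(NULL)
    }
    hit[1]
  }
  uname <- pick(vm$u, "eastward velocity")
  vname <- pick(vm$v, "northward velocity")
  mname <- pick(vm$landmask, "landmask", required = FALSE)
  for (nm in c(uname, vname)) {
    un <- nc$var[[nm]]$units
    if (nzchar(un) && !velocity_units_ok(un)) {
      stop("read_currents: variable ", nm, " has units '", un,
           "', expected m/s")
    }
  }
  dims <- nc$var[[uname]]$dim
  dnames <- vapply(dims, function(d) d$name, character(1))
  lon_i <- grep("^(lon|longitude|x)$", dnames, ignore.case = TRUE)
  lat_i <- grep("^(lat|latitude|y)$", dnames, ignore.case = TRUE)
  tim_i <- grep("^(time|t)$", dnames, ignore.case = TRUE)
  if (length(lon_i) != 1 || length(lat_i) != 1 || length(tim_i) != 1) {
    stop("read_currents: expected (longitude, latitude, time) dimensions, got: ",
         paste(dnames, collapse = ", "))
  }
  lon <- as.vector(dims[[lon_i]]$vals); lat <- as.vector(dims[[lat_i]]$vals)
  times <- parse_time_units(dims[[tim_i]]$units,
                            as.vector(dims[[tim_i]]$vals))
  if (any(diff(lon) <= 0)) stop("read_currents: longitude not strictly increasing")
  flip <- FALSE
  if (all(diff(lat) < 0)) { lat <- rev(lat); flip <- TRUE }
  if (any(diff(lat) <= 0)) stop("read_currents: latitude not monotone")
  u <- ncdf4::ncvar_get(nc, uname, collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, vname, collapse_degen = FALSE)
  perm <- c(lon_i, lat_i, tim_i)
  if (!identical(perm, 1:3)) { u <- aperm(u, perm); v <- aperm(v, perm) }
  if (flip) {
    u <- u[, rev(seq_along(lat)), , drop = FALSE]
    v <- v[, rev(seq_along(lat)), , drop = FALSE]
  }
  if (!is.null(mname)) {
    mk <- ncdf4::ncvar_get(nc, mname, collapse_degen = FALSE)
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    if (flip) mk <- mk[, rev(seq_along(lat))]
    mask <- mk > 0.5
  } else {
    mask <- apply(is.na(u) | is.na(v), c(1, 2), any)
  }
  mask <- mask | apply(is.na(u) | is.na(v), c(1, 2), any)
  u[array(mask, dim(u))] <- NA_real_
  v[array(mask, dim(v))] <- NA_real_
  g <- grid_spec(lon[1], lon[length(lon)], mean(diff(lon)),
                 lat[1], lat[length(lat)], mean(diff(lat)), times)
  ## guard against seq() dropping a node through rounding
  g$lon <- lon; g$lat <- lat
  flow_field(g, u, v, mask)
}

## fractional grid coordinates; NA outside the hull
frac_index <- function(coord, x) {
  f <- (x - coord[1]) / mean(diff(coord))
  f[x < coord[1] | x > coord[length(coord)]] <- NA_real_
  f
}

#' Sample velocity continuously in space and time
#'
#' Bilinear interpolation in space and linear interpolation in time between
#' the two bracketing snapshots. Land corner nodes contribute zero velocity
#' and their bilinear weight is renormalised over the ocean corners, which
#' avoids spurious onshore drift near the coast. Queries outside the spatial
#' hull or time span return \code{NA} (the tracker treats this as a domain
#' exit). \code{field} may also be a function \code{(lon, lat, t) ->
#' list(u, v)} for analytic test fields.
#'
#' @param field a \code{\link{flow_field}} or a sampler function.
#' @param lon,lat query points, degrees (vectorised).
#' @param t query time, POSIXct or numeric seconds (scalar or vectorised).
#' @return list(u, v) in m/s.
#' @export
sample_velocity <- function(field, lon, lat, t) {
  if (is.function(field)) return(field(lon, lat, t))
  g <- field$grid
  n <- length(lon)
  t <- as.numeric(t)
  if (length(t) == 1) t <- rep(t, n)
  tg <- as.numeric(g$times)
  nlon <- length(g$lon); nlat <- length(g$lat); nt <- length(tg)

  fx <- frac_index(g$lon, lon)
  fy <- frac_index(g$lat, lat)
  ft <- if (nt == 1) ifelse(abs(t - tg[1]) < 1e-6, 0, NA_real_) else
    (t - tg[1]) / (tg[2] - tg[1])
  if (nt > 1) ft[t < tg[1] - 1e-6 | t > tg[nt] + 1e-6] <- NA_real_
  bad <- is.na(fx) | is.na(fy) | is.na(ft)

  ix <- pmin(pmax(floor(fx), 0), nlon - 2); wx <- fx - ix
  jy <- pmin(pmax(floor(fy), 0), nlat - 2); wy <- fy - jy
  kt <- pmin(pmax(floor(ft), 0), max(nt - 2, 0)); wt <- ft - kt
  ix[bad] <- 0; jy[bad] <- 0; kt[bad] <- 0
  wx[bad] <- 0; wy[bad] <- 0; wt[bad] <- 0

  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy;       w11 <- wx * wy
  base <- function(di, dj, dk) (ix + di + 1) + (jy + dj) * nlon +
    (kt + dk) * nlon * nlat
  mbase <- function(di, dj) (ix + di + 1) + (jy + dj) * nlon
  mk <- field$landmask
  o00 <- !mk[mbase(0, 0)]; o10 <- !mk[mbase(1, 0)]
  o01 <- !mk[mbase(0, 1)]; o11 <- !mk[mbase(1, 1)]
  interp_slice <- function(arr, dk) {
    i00 <- base(0, 0, dk); i10 <- base(1, 0, dk)
    i01 <- base(0, 1, dk); i11 <- base(1, 1, dk)
    wsum <- w00 * o00 + w10 * o10 + w01 * o01 + w11 * o11
    val <- w00 * ifelse(o00, arr[i00], 0) + w10 * ifelse(o10, arr[i10], 0) +
           w01 * ifelse(o01, arr[i01], 0) + w11 * ifelse(o11, arr[i11], 0)
    ifelse(wsum > 0, val / wsum, 0)
  }
  dk1 <- if (nt == 1) 0 else 1
  u <- (1 - wt) * interp_slice(field$u, 0) + wt * interp_slice(field$u, dk1)
  v <- (1 - wt) * interp_slice(field$v, 0) + wt * interp_slice(field$v, dk1)
  u[bad] <- NA_real_; v[bad] <- NA_real_
  list(u = u, v = v)
}

## 0 = ocean, 1 = land (nearest node), 2 = outside hull; vectorised
ocean_code <- function(field, lon, lat) {
  g <- field$grid
  fx <- frac_index(g$lon, lon)
  fy <- frac_index(g$lat, lat)
  out <- is.na(fx) | is.na(fy)
  ix <- pmin(pmax(round(fx), 0), length(g$lon) - 1) + 1
  jy <- pmin(pmax(round(fy), 0), length(g$lat) - 1) + 1
  ix[out] <- 1; jy[out] <- 1
  code <- ifelse(field$landmask[cbind(ix, jy)], 1L, 0L)
  code[out] <- 2L
  code
}

#' Is a point in the ocean?
#'
#' Nearest-node landmask test. Points outside the grid hull return
#' \code{FALSE} with attribute \code{outside} set \code{TRUE}.
#'
#' @param field a \code{\link{flow_field}}.
#' @param lon,lat query points, degrees.
#' @return logical vector with attribute \code{outside}.
#' @export
is_ocean <- function(field, lon, lat) {
  code <- ocean_code(field, lon, lat)
  structure(code == 0L, outside = code == 2L)
}

#' @export
plot.flow_field <- function(x, time_index = 1, every = 4, ...) {
  g <- x$grid
  sp <- sqrt(x$u[, , time_index]^2 + x$v[, , time_index]^2)
  graphics::image(g$lon, g$lat, sp, col = grDevices::hcl.colors(64, "Blues 3",
                                                                rev = TRUE),
                  xlab = "longitude", ylab = "latitude",
                  main = sprintf("surface speed (m/s), %s",
                                 format(g$times[time_index], "%Y-%m-%d")), ...)
  land <- ifelse(x$landmask, 1, NA)
  graphics::image(g$lon, g$lat, land, col = "grey60", add = TRUE)
  ii <- seq(1, length(g$lon), by = every); jj <- seq(1, length(g$lat), by = every)
  lonm <- matrix(g$lon[ii], length(ii), length(jj))
  latm <- matrix(g$lat[jj], length(ii), length(jj), byrow = TRUE)
  uu <- x$u[ii, jj, time_index]; vv <- x$v[ii, jj, time_index]
  sc <- 0.3 / max(sp, na.rm = TRUE)
  ok <- is.finite(uu) & is.finite(vv) & (abs(uu) + abs(vv) > 0)
  graphics::arrows(lonm[ok], latm[ok], lonm[ok] + sc * uu[ok],
                   latm[ok] + sc * vv[ok], length = 0.02, col = "grey20")
  invisible(x)
}
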