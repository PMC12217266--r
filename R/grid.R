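#' Regular longitude/latitude grid with a daily time axis
#'
#' Defines the discretisation on which synthetic current fields are generated
#' and on which gridded products are stored: a regular lon/lat node grid plus
#' an ordered, uniformly spaced vector of snapshot times (daily by default,
#' mirroring daily-averaged reanalysis output).
#'
#' @param lon_min,lon_max,dlon longitude extent and node spacing, degrees east.
#' @param lat_min,lat_max,dlat latitude extent and node spacing, degrees north.
#' @param times ordered POSIXct (or coercible) snapshot times, uniformly
#'   spaced and strictly increasing.
#' @return object of class \code{grid_spec} with node vectors \code{lon},
#'   \code{lat} and the \code{times} axis.
#' @examples
#' g <- grid_spec(32, 36, 1 / 24, -28, -20, 1 / 24,
#'                times = as.POSIXct("2010-02-01", tz = "UTC") + 86400 * 0:19)
#' @export
grid_spec <- function(lon_min, lon_max, dlon, lat_min, lat_max, dlat, times) {
  stop_if_not(dlon > 0 && dlat > 0, "grid_spec: dlon and dlat must be positive")
  lon <- seq(lon_min, lon_max, by = dlon)
  lat <- seq(lat_min, lat_max, by = dlat)
  stop_if_not(length(lon) >= 2 && length(lat) >= 2,
              "grid_spec: need at least 2 nodes per axis")
  times <- as_utc(times)
  tn <- as.numeric(times)
  stop_if_not(length(times) >= 1 && all(diff(tn) > 0),
              "grid_spec: times must be strictly increasing")
  if (length(tn) > 2) {
    dts <- diff(tn)
    stop_if_not(max(abs(dts - dts[1])) < 1e-6,
                "grid_spec: times must be uniformly spaced")
  }
  structure(list(lon = lon, lat = lat, dlon = dlon, dlat = dlat,
                 times = times),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d nodes, lon [%g, %g] x lat [%g, %g], %d time steps\n",
              length(x$lon), length(x$lat),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat), length(x$times)))
  invisible(x)
}

#' Idealised coastline with a bight-forming headland
#'
#' A meridional coastline (land to the west) carrying a smooth eastward
#' undulation: over a latitude band of the given half-width the coast is
#' displaced east by up to \code{indentation_deg} (a cosine bell), producing a
#' headland whose concave flanks form the bight. This emulates the coastline
#' undulation that deflects alongshore currents and casts the lee zone in
#' which cyclonic eddies sit.
#'
#' @param coast_lon longitude of the undisturbed meridional coastline.
#' @param bight_lat latitude of the centre of the undulation.
#' @param half_width_deg half-width of the undulation band, degrees (> 0).
#' @param indentation_deg maximum eastward displacement of the coast,
#'   degrees (>= 0); 0 gives a straight coastline.
#' @return object of class \code{bight_coast}.
#' @export
bight_coast <- function(coast_lon = 33.0, bight_lat = -23.0,
                        half_width_deg = 1.6, indentation_deg = 1.0) {
  stop_if_not(half_width_deg > 0, "bight_coast: half_width_deg must be > 0")
  stop_if_not(indentation_deg >= 0, "bight_coast: indentation_deg must be >= 0")
  structure(list(coast_lon = coast_lon, bight_lat = bight_lat,
                 half_width_deg = half_width_deg,
                 indentation_deg = indentation_deg),
            class = "bight_coast")
}

#' Coastline longitude as a function of latitude
#'
#' @param coast a \code{\link{bight_coast}}.
#' @param lat latitude vector, degrees.
#' @return longitude of the land/ocean boundary at each latitude; land lies at
#'   longitudes strictly west of this curve.
#' @export
coastline_lon <- function(coast, lat) {
  s <- (lat - coast$bight_lat) / coast$half_width_deg
  bump <- ifelse(abs(s) < 1, 0.5 * (1 + cos(pi * s)), 0)
  coast$coast_lon + coast$indentation_deg * bump
}

#' Rasterise the coastline into a landmask
#'
#' Classifies every grid node as land or ocean by direct evaluation of the
#' coastline curve. The mask is time invariant.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param coast a \code{\link{bight_coast}}.
#' @return logical matrix \code{[lon, lat]}; \code{TRUE} = land.
#' @export
make_landmask <- function(grid, coast) {
  cl <- coastline_lon(coast, grid$lat)
  mask <- outer(grid$lon, cl, function(lon, c) lon < c)
  if (all(mask)) stop("make_landmask: degenerate domain (grid entirely land)")
  dimnames(mask) <- NULL
  mask
}
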