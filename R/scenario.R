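## Synthetic flow scenarios are built from analytic streamfunctions so the
## generated currents are non-divergent by construction: u = -dpsi/dy,
## v = +dpsi/dx (local metres). Components: uniform drift, Rankine vortex,
## Gaussian jet along a waypoint path. Each component carries an optional
## piecewise-linear amplitude modulation in time (eddy arrival/decay).

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Uniform background drift component
#'
#' @param u,v eastward/northward drift, m/s.
#' @param ref_lat latitude (degrees) at which the meridional drift equals
#'   \code{v} exactly; defaults to 0.
#' @param modulation optional list(time = POSIXct, amp = numeric) of
#'   piecewise-linear amplitude breakpoints (constant 1 if NULL).
#' @return a \code{flow_component}.
#' @export
flow_uniform <- function(u, v, ref_lat = 0, modulation = NULL) {
  stop_if_not(is.finite(u) && is.finite(v), "flow_uniform: drift must be finite")
  structure(list(kind = "uniform", u = u, v = v, ref_lat = ref_lat,
                 modulation = modulation),
            class = "flow_component")
}

#' Rankine vortex component
#'
#' Idealised mesoscale eddy: solid-body rotation inside the core radius,
#' azimuthal speed decaying as 1/r outside. \code{rotation = +1} is
#' counterclockwise (Southern-Hemisphere anticyclone), \code{-1} clockwise
#' (Southern-Hemisphere cyclone).
#'
#' @param lon,lat vortex centre, degrees.
#' @param radius_km core radius, km (> 0).
#' @param peak_ms azimuthal speed at the core edge, m/s.
#' @param rotation +1 (counterclockwise) or -1 (clockwise).
#' @param modulation optional amplitude breakpoints as in
#'   \code{\link{flow_uniform}}.
#' @export
flow_rankine <- function(lon, lat, radius_km, peak_ms, rotation = 1,
                         modulation = NULL) {
  stop_if_not(radius_km > 0, "flow_rankine: radius_km must be > 0")
  stop_if_not(is.finite(peak_ms), "flow_rankine: peak speed must be finite")
  stop_if_not(rotation %in% c(-1, 1), "flow_rankine: rotation must be +1 or -1")
  structure(list(kind = "rankine_vortex", lon = lon, lat = lat,
                 radius_m = radius_km * 1000, peak = peak_ms,
                 rotation = rotation, modulation = modulation),
            class = "flow_component")
}

#' Gaussian jet along a waypoint path
#'
#' A stream with Gaussian cross-track speed profile (peak on the axis,
#' e-folding set by \code{width_km}) flowing in the direction of the waypoint
#' sequence. The streamfunction is an error-function profile of the signed
#' cross-track distance, so the jet is non-divergent.
#'
#' @param waypoints two-column matrix (lon, lat) of path vertices, in flow
#'   direction order.
#' @param width_km cross-track standard-deviation width, km (> 0).
#' @param peak_ms axis speed, m/s.
#' @param modulation optional amplitude breakpoints.
#' @export
flow_jet <- function(waypoints, width_km, peak_ms, modulation = NULL) {
  waypoints <- as.matrix(waypoints)
  stop_if_not(ncol(waypoints) == 2 && nrow(waypoints) >= 2,
              "flow_jet: waypoints must be a (>=2) x 2 matrix")
  stop_if_not(width_km > 0, "flow_jet: width_km must be > 0")
  stop_if_not(is.finite(peak_ms), "flow_jet: peak speed must be finite")
  structure(list(kind = "gaussian_jet", waypoints = waypoints,
                 width_m = width_km * 1000, peak = peak_ms,
                 modulation = modulation),
            class = "flow_component")
}

#' Assemble a flow scenario
#'
#' @param components list of \code{flow_component}s (at least one).
#' @param coast a \code{\link{bight_coast}} defining the landmask.
#' @return object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(components, coast = bight_coast()) {
  if (inherits(components, "flow_component")) components <- list(components)
  stop_if_not(length(components) >= 1,
              "scenario_spec: need at least one flow component")
  ok <- vapply(components, inherits, logical(1), what = "flow_component")
  stop_if_not(all(ok), "scenario_spec: all components must be flow_component")
  structure(list(components = components, coast = coast),
            class = "scenario_spec")
}

## amplitude of a component at time t (numeric seconds), vectorised in t
component_amp <- function(comp, t) {
  m <- comp$modulation
  if (is.null(m)) return(rep(1, length(t)))
  stats::approx(as.numeric(as_utc(m$time)), m$amp, xout = t, rule = 2)$y
}

## signed cross-track distance (m) to a polyline; positive left of the
## flow direction. Vectorised over query points.
jet_cross_track <- function(waypoints, lon, lat) {
  ref_lat <- mean(waypoints[, 2])
  kx <- m_per_deg_lon(ref_lat); ky <- m_per_deg_lat()
  wx <- (waypoints[, 1] - waypoints[1, 1]) * kx
  wy <- (waypoints[, 2] - waypoints[1, 2]) * ky
  qx <- (lon - waypoints[1, 1]) * kx
  qy <- (lat - waypoints[1, 2]) * ky
  best <- rep(Inf, length(qx))
  sgn <- rep(1, length(qx))
  for (k in seq_len(nrow(waypoints) - 1)) {
    dx <- wx[k + 1] - wx[k]; dy <- wy[k + 1] - wy[k]
    len2 <- dx * dx + dy * dy
    tt <- pmin(1, pmax(0, ((qx - wx[k]) * dx + (qy - wy[k]) * dy) / len2))
    fx <- wx[k] + tt * dx; fy <- wy[k] + tt * dy
    d2 <- (qx - fx)^2 + (qy - fy)^2
    cr <- dx * (qy - fy) - dy * (qx - fx)   # >0: point left of segment
    upd <- d2 < best
    best[upd] <- d2[upd]
    sgn[upd] <- ifelse(cr[upd] >= 0, 1, -1)
  }
  sgn * sqrt(best)
}

component_psi <- function(comp, lon, lat) {
  switch(comp$kind,
    uniform = {
      y <- lat * m_per_deg_lat()
      xeq <- lon * (EARTH_RADIUS * pi / 180)
      -comp$u * y + comp$v * cos(comp$ref_lat * pi / 180) * xeq
    },
    rankine_vortex = {
      x <- (lon - comp$lon) * m_per_deg_lon(comp$lat)
      y <- (lat - comp$lat) * m_per_deg_lat()
      r <- sqrt(x * x + y * y)
      R <- comp$radius_m; V <- comp$peak
      psi <- ifelse(r < R,
                    V * r * r / (2 * R),
                    V * R / 2 + V * R * log(pmax(r, .Machine$double.eps) / R))
      comp$rotation * psi
    },
    gaussian_jet = {
      n <- jet_cross_track(comp$waypoints, lon, lat)
      W <- comp$width_m
      -comp$peak * W * sqrt(pi / 2) * erf(n / (sqrt(2) * W))
    },
    stop("unknown flow component kind: ", comp$kind)
  )
}

#' Evaluate the scenario streamfunction
#'
#' Pure function: the sum of the component streamfunctions, each scaled by its
#' amplitude modulation at time \code{t}. Units m^2/s. With all amplitudes
#' zero the streamfunction vanishes identically.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param lon,lat evaluation points, degrees (vectorised).
#' @param t time (POSIXct or numeric seconds), scalar or vectorised with the
#'   points.
#' @return numeric vector of psi values, m^2/s.
#' @export
streamfunction <- function(spec, lon, lat, t) {
  t <- if (inherits(t, "POSIXct")) as.numeric(t) else as.numeric(t)
  psi <- numeric(length(lon))
  for (comp in spec$components) {
    a <- component_amp(comp, t)
    psi <- psi + a * component_psi(comp, lon, lat)
  }
  psi
}

#' Analytic velocity of a scenario (for oracle use)
#'
#' Velocity at points by central differencing of the continuum streamfunction
#' with a small stencil; used as a smooth sampler independent of any grid.
#' @param spec a \code{scenario_spec}.
#' @param lon,lat,t as in \code{\link{streamfunction}}.
#' @param eps_m stencil half-width in metres.
#' @return list(u, v) in m/s.
#' @export
scenario_velocity <- function(spec, lon, lat, t, eps_m = 50) {
  dl <- meters_to_degrees(eps_m, eps_m, lat)
  u <- -(streamfunction(spec, lon, lat + dl$dlat, t) -
         streamfunction(spec, lon, lat - dl$dlat, t)) / (2 * eps_m)
  v <- (streamfunction(spec, lon + dl$dlon, lat, t) -
        streamfunction(spec, lon - dl$dlon, lat, t)) / (2 * eps_m)
  list(u = u, v = v)
}
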