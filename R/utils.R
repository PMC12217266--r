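#' @keywords internal
"_PACKAGE"

## Mean Earth radius used for all degree <-> metre conversions (m).
EARTH_RADIUS <- 6371000

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; seeding counts use the
#' conventional "half away from zero" rule instead.
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## metres spanned by one degree of latitude
m_per_deg_lat <- function() EARTH_RADIUS * pi / 180

## metres spanned by one degree of longitude at latitude `lat`
m_per_deg_lon <- function(lat) EARTH_RADIUS * cos(lat * pi / 180) * pi / 180

#' Convert metre displacements to degree displacements
#'
#' @param dx_m,dy_m eastward / northward displacements in metres.
#' @param lat latitude in degrees at which the conversion applies
#'   (must satisfy \code{abs(lat) < 89}).
#' @return list with components \code{dlon}, \code{dlat} in degrees.
#' @examples
#' meters_to_degrees(0, 6371000 * pi / 180, 0) # dlat = 1 degree
#' @export
meters_to_degrees <- function(dx_m, dy_m, lat) {
  if (any(abs(lat) >= 89)) {
    stop("meters_to_degrees: latitude too close to the pole (|lat| >= 89)")
  }
  list(dlon = dx_m / m_per_deg_lon(lat), dlat = dy_m / m_per_deg_lat())
}

## ISO timestamp -> POSIXct UTC
as_utc <- function(x) as.POSIXct(x, tz = "UTC")

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
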