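## Three canonical regional flow regimes for the idealised bight domain.
## A: slow alongshore stream hugging the coastline undulation; connects
##    neighbouring bands only (transit between distant bands exceeds the PLD).
## B: fast direct stream from the headland to the southern reefs, bypassing
##    the bight, plus a cyclonic lee eddy that spins up inside the bight and
##    traps larvae released there.
## C: broad western-boundary-style coastal stream (>= 1.5 m/s) fed by the
##    flank of a large offshore anticyclone; connects the most distant bands
##    within the settlement window.

#' Default synthetic domain grid
#'
#' About 4 x 8.5 degrees at 1/24 degree with daily snapshots: fine enough to
#' resolve the eddy cores by >= 8 nodes while keeping runs at desk scale.
#'
#' @param start first snapshot time (default 2010-02-01 00:00 UTC).
#' @param n_days number of daily snapshots.
#' @param resolution node spacing in degrees.
#' @return a \code{\link{grid_spec}}.
#' @export
default_grid <- function(start = "2010-02-01", n_days = 20,
                         resolution = 1 / 24) {
  times <- as_utc(start) + 86400 * (seq_len(n_days) - 1)
  grid_spec(32.5, 36.5, resolution, -28.5, -20, resolution, times)
}

## coast-hugging waypoint path, offset east of the coastline
coastal_path <- function(coast, lats, offset_deg = 0.25) {
  cbind(coastline_lon(coast, lats) + offset_deg, lats)
}

## default alongshore reef band latitudes, north to south
default_band_lats <- function() {
  c(BA = -21.3, INHM = -23.0, INHC = -25.5, MRC = -27.3)
}

#' Canonical flow scenarios A, B, C
#'
#' @param name "A", "B" or "C".
#' @param times snapshot times used to anchor amplitude modulations
#'   (default those of \code{\link{default_grid}}).
#' @param coast the \code{\link{bight_coast}} (default domain coastline).
#' @return a \code{\link{scenario_spec}}.
#' @export
scenario_library <- function(name, times = default_grid()$times,
                             coast = bight_coast()) {
  times <- as_utc(times)
  t0 <- times[1]
  ## jet paths extend past the grid so their end caps (where the
  ## streamfunction's return flow concentrates) lie outside the domain
  lats <- seq(-19.6, -29.2, by = -0.45)
  along <- coastal_path(coast, lats, 0.25)
  comps <- switch(as.character(name),
    A = list(
      flow_jet(along, width_km = 35, peak_ms = 0.3)
    ),
    B = list(
      flow_jet(rbind(c(34.15, -19.6), c(34.22, -21.6), c(34.25, -22.6),
                     c(34.30, -23.6), c(34.10, -25.0), c(33.70, -26.3),
                     c(33.25, -27.4), c(33.05, -29.0)),
               width_km = 40, peak_ms = 1.0),
      flow_rankine(33.5, -24.5, radius_km = 60, peak_ms = 0.35,
                   rotation = -1,   # Southern-Hemisphere cyclone (clockwise)
                   modulation = list(time = c(t0, t0 + 4 * 86400),
                                     amp = c(0.3, 1.0)))
    ),
    C = list(
      flow_jet(along, width_km = 45, peak_ms = 1.4),
      flow_rankine(35.6, -24.5, radius_km = 180, peak_ms = 0.5,
                   rotation = 1)    # Southern-Hemisphere anticyclone
    ),
    stop("scenario_library: unknown scenario '", name, "' (use A, B or C)")
  )
  scenario_spec(comps, coast)
}
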