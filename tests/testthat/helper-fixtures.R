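## fixtures are built in code; oracles here are written independently of the
## package internals they check (different algorithms on purpose)

t0 <- as.POSIXct("2010-02-01", tz = "UTC")

## coastline far west of every test grid -> all-ocean domain
open_ocean <- function() bight_coast(coast_lon = -10, indentation_deg = 0)

daily <- function(n, start = t0) start + 86400 * (seq_len(n) - 1)

## small all-ocean grid around the equator
eq_grid <- function(lon_max = 4, lat_half = 2, res = 1 / 24, n_days = 12) {
  grid_spec(0, lon_max, res, -lat_half, lat_half, res, daily(n_days))
}

uniform_field <- function(u, v, grid = eq_grid(), coast = open_ocean()) {
  velocity_field(scenario_spec(flow_uniform(u, v), coast), grid)
}

axis_square <- function(id, cx, lon_c, lat_c, half_lon, half_lat = half_lon) {
  reef_polygon(id, cx,
               lon_c + c(-1, 1, 1, -1) * half_lon,
               lat_c + c(-1, -1, 1, 1) * half_lat)
}

## --- independent oracles ----------------------------------------------------

## winding-angle point-in-polygon (different algorithm from the package's
## even-odd ray casting); vectorised over points
oracle_in_polygon <- function(lon, lat, plon, plat) {
  total <- numeric(length(lon))
  n <- length(plon)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ax <- plon[i] - lon; ay <- plat[i] - lat
    bx <- plon[j] - lon; by <- plat[j] - lat
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  abs(total) > pi
}

## brute-force scan over every polygon in set order
oracle_locate <- function(lon, lat, reefs) {
  out <- rep(NA_character_, length(lon))
  for (k in seq_along(reefs$polygons)) {
    p <- reefs$polygons[[k]]
    hit <- is.na(out) & oracle_in_polygon(lon, lat, p$lon, p$lat)
    out[hit] <- p$reef_id
  }
  out
}

## nested-loop bilinear-in-space, linear-in-time interpolation with
## land-weight renormalisation (scalar, slow on purpose)
oracle_sample <- function(field, lon, lat, t) {
  g <- field$grid
  tg <- as.numeric(g$times)
  t <- as.numeric(t)
  interp_one <- function(arr2d, fx, fy) {
    i <- floor(fx); j <- floor(fy)
    i <- min(max(i, 0), length(g$lon) - 2)
    j <- min(max(j, 0), length(g$lat) - 2)
    wx <- fx - i; wy <- fy - j
    tot <- 0; wsum <- 0
    for (di in 0:1) for (dj in 0:1) {
      w <- (if (di == 0) 1 - wx else wx) * (if (dj == 0) 1 - wy else wy)
      if (!field$landmask[i + di + 1, j + dj + 1]) {
        tot <- tot + w * arr2d[i + di + 1, j + dj + 1]
        wsum <- wsum + w
      }
    }
    if (wsum > 0) tot / wsum else 0
  }
  u <- numeric(length(lon)); v <- numeric(length(lon))
  for (q in seq_along(lon)) {
    fx <- (lon[q] - g$lon[1]) / g$dlon
    fy <- (lat[q] - g$lat[1]) / g$dlat
    tq <- if (length(t) == 1) t else t[q]
    ft <- (tq - tg[1]) / (tg[2] - tg[1])
    k <- min(max(floor(ft), 0), length(tg) - 2)
    wt <- ft - k
    u[q] <- (1 - wt) * interp_one(field$u[, , k + 1], fx, fy) +
      wt * interp_one(field$u[, , k + 2], fx, fy)
    v[q] <- (1 - wt) * interp_one(field$v[, , k + 1], fx, fy) +
      wt * interp_one(field$v[, , k + 2], fx, fy)
  }
  list(u = u, v = v)
}

## independent first-contact scan of a trajectory batch against reef polygons
oracle_events <- function(traj, reefs, pre_days = 4, pld_days = 10) {
  out <- list()
  for (b in traj$batches) {
    ages <- b$times - b$times[1]
    for (p in seq_len(nrow(b$lon))) {
      seen <- character(0)
      for (cc in seq_along(b$times)) {
        if (ages[cc] < pre_days * 86400 || ages[cc] > pld_days * 86400) next
        if (b$status[p, cc] != 0) next
        for (k in seq_along(reefs$polygons)) {
          pol <- reefs$polygons[[k]]
          if (reefs$reef_ids[k] %in% seen) next
          if (oracle_in_polygon(b$lon[p, cc], b$lat[p, cc], pol$lon, pol$lat)) {
            seen <- c(seen, reefs$reef_ids[k])
            out[[length(out) + 1]] <- data.frame(
              particle_id = b$particle_id[p], dest_reef = reefs$reef_ids[k],
              travel_time_h = ages[cc] / 3600)
          }
        }
      }
    }
  }
  if (length(out) == 0) return(data.frame(particle_id = character(),
                                          dest_reef = character(),
                                          travel_time_h = numeric()))
  do.call(rbind, out)
}
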