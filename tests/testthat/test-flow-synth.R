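test_that("landmask matches direct evaluation of the coastline curve", {
  coast <- bight_coast(coast_lon = 33, bight_lat = -23, half_width_deg = 1.6,
                       indentation_deg = 1)
  g <- grid_spec(31.5, 35.5, 4 / 19, -25, -21, 4 / 19, daily(1))
  mask <- make_landmask(g, coast)
  expect_equal(dim(mask), c(20, 20))
  for (i in seq_along(g$lon)) {
    for (j in seq_along(g$lat)) {
      s <- (g$lat[j] - coast$bight_lat) / coast$half_width_deg
      cl <- coast$coast_lon +
        coast$indentation_deg * if (abs(s) < 1) 0.5 * (1 + cos(pi * s)) else 0
      expect_identical(mask[i, j], g$lon[i] < cl)
    }
  }
  ## a node between the straight coastline and the displaced coast at the
  ## bight centre lies on the recessed side -> land
  expect_true(mask[which.min(abs(g$lon - 33.5)), which.min(abs(g$lat + 23))])
})

test_that("straight coastline gives a half-plane mask; all-land errors", {
  coast <- bight_coast(coast_lon = 33, indentation_deg = 0)
  g <- grid_spec(32, 34, 0.1, -25, -24, 0.1, daily(1))
  mask <- make_landmask(g, coast)
  expect_identical(mask, outer(g$lon, g$lat, function(x, y) x < 33))
  all_land <- bight_coast(coast_lon = 99, indentation_deg = 0)
  expect_error(make_landmask(g, all_land), "degenerate domain")
})

test_that("streamfunction is linear in components and zero with zero amplitude", {
  c1 <- flow_rankine(2, 0, 50, 0.5)
  c2 <- flow_uniform(0.2, -0.1)
  off <- list(time = c(t0, t0 + 86400), amp = c(0, 0))
  lon <- runif(20, 0, 4); lat <- runif(20, -2, 2)
  expect_equal(streamfunction(scenario_spec(flow_rankine(2, 0, 50, 0.5,
                                                         modulation = off)),
                              lon, lat, t0),
               rep(0, 20))
  p12 <- streamfunction(scenario_spec(list(c1, c2)), lon, lat, t0)
  p1 <- streamfunction(scenario_spec(c1), lon, lat, t0)
  p2 <- streamfunction(scenario_spec(c2), lon, lat, t0)
  expect_equal(p12, p1 + p2)
})

test_that("Rankine core streamfunction difference equals V R / 2", {
  V <- 0.7; R_km <- 40
  sc <- scenario_spec(flow_rankine(2, 0, R_km, V))
  edge_lon <- 2 + R_km * 1000 / m_per_deg_lon(0)
  dpsi <- streamfunction(sc, edge_lon, 0, t0) - streamfunction(sc, 2, 0, t0)
  expect_equal(dpsi, V * R_km * 1000 / 2, tolerance = 1e-9)
})

test_that("uniform-drift field reproduces the drift at ocean nodes", {
  f <- uniform_field(0.4, 0, grid = eq_grid(n_days = 2))
  expect_equal(max(abs(f$u - 0.4), na.rm = TRUE), 0, tolerance = 1e-6)
  expect_equal(max(abs(f$v), na.rm = TRUE), 0, tolerance = 1e-6)
})

test_that("gridded Rankine vortex peaks at the core radius with the right speed", {
  V <- 0.8; R_km <- 50           # core resolved by ~21 nodes at 1/48 degree
  g <- eq_grid(res = 1 / 48, n_days = 1)
  f <- velocity_field(scenario_spec(flow_rankine(2, 0, R_km, V),
                                    open_ocean()), g)
  sp <- sqrt(f$u[, , 1]^2 + f$v[, , 1]^2)
  i <- which(sp == max(sp), arr.ind = TRUE)
  r_m <- sqrt(((g$lon[i[1]] - 2) * m_per_deg_lon(0))^2 +
              (g$lat[i[2]] * m_per_deg_lat())^2)
  expect_lt(abs(max(sp) - V) / V, 0.02)
  expect_lt(abs(r_m - R_km * 1000), 1.5 * g$dlon * m_per_deg_lon(0))
})

test_that("generated fields are discretely non-divergent (independent stencil)", {
  g <- default_grid(n_days = 2)
  for (s in c("A", "B", "C")) {
    f <- velocity_field(scenario_library(s, g$times), g)
    u <- f$u[, , 1]; v <- f$v[, , 1]
    coslat <- cos(g$lat * pi / 180)
    dxeq <- g$dlon * pi / 180 * 6371000
    dy <- g$dlat * pi / 180 * 6371000
    ## nested-loop spherical divergence on a subsample of interior ocean nodes
    set.seed(11)
    ii <- sample(2:(length(g$lon) - 1), 40)
    jj <- sample(2:(length(g$lat) - 1), 40)
    peak_over_radius <- 1.6 / 40e3   # scale: fastest eddy over smallest core
    for (q in seq_along(ii)) {
      i <- ii[q]; j <- jj[q]
      vals <- c(u[i + 1, j], u[i - 1, j], v[i, j + 1], v[i, j - 1])
      if (any(is.na(vals)) || is.na(u[i, j])) next
      div <- ((u[i + 1, j] - u[i - 1, j]) / (2 * dxeq) +
              (v[i, j + 1] * coslat[j + 1] - v[i, j - 1] * coslat[j - 1]) /
                (2 * dy)) / coslat[j]
      expect_lt(abs(div), 1e-6 * peak_over_radius)
    }
  }
})

test_that("scenario library encodes the three flow regimes", {
  g <- default_grid(n_days = 2)
  maxspeed <- function(s) {
    f <- velocity_field(scenario_library(s, g$times), g)
    max(sqrt(f$u^2 + f$v^2), na.rm = TRUE)
  }
  expect_gte(maxspeed("C"), 1.5)        # western-boundary-style stream
  expect_lt(maxspeed("A"), maxspeed("B"))
  expect_error(scenario_library("D"), "unknown scenario")

  ## scenario B: closed cyclonic cell inside the bight -- the velocity vector
  ## winds once around a circuit surrounding the eddy centre
  f <- velocity_field(scenario_library("B", g$times), g)
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  r_deg <- 0.3
  clon <- 33.5 + r_deg * cos(theta); clat <- -24.5 + r_deg * sin(theta)
  vel <- sample_velocity(f, clon, clat, g$times[2])
  ang <- atan2(vel$v, vel$u)
  dang <- diff(c(ang, ang[1]))
  dang <- ((dang + pi) %% (2 * pi)) - pi
  expect_equal(abs(sum(dang) / (2 * pi)), 1, tolerance = 1e-6)
  ## clockwise (Southern-Hemisphere cyclonic) circulation: negative
  tang <- -sin(theta) * vel$u + cos(theta) * vel$v
  expect_lt(mean(tang), 0)
})

test_that("generated reefs sit in ocean, in ordered bands, deterministically", {
  coast <- bight_coast()
  r1 <- generate_reefs(coast, n_per_complex = 3, seed = 5)
  r2 <- generate_reefs(coast, n_per_complex = 3, seed = 5)
  expect_identical(r1, r2)
  r3 <- generate_reefs(coast, n_per_complex = 3, seed = 6)
  expect_false(identical(r1, r3))
  for (p in r1$polygons) {
    expect_true(all(p$lon > coastline_lon(coast, p$lat)))
  }
  ## complex bands strictly ordered north -> south
  lat_by_cx <- tapply(vapply(r1$polygons, function(p) p$centroid[["lat"]],
                             numeric(1)),
                      factor(r1$complex_ids, levels = unique(r1$complex_ids)),
                      range)
  for (k in seq_len(length(lat_by_cx) - 1)) {
    expect_gt(min(lat_by_cx[[k]]), max(lat_by_cx[[k + 1]]))
  }
  expect_true(all(r1$areas_km2 > 0.2 & r1$areas_km2 < 3))
  ## impossible placement (forced onto land) errors out
  expect_error(generate_reefs(coast, 1, offshore_deg = c(-3, -2.9)),
               "could not place")
})

test_that("currents round-trip through NetCDF bit-for-float", {
  g <- grid_spec(0, 1, 0.25, 0, 1, 0.25, daily(3))
  f <- velocity_field(scenario_spec(flow_rankine(0.5, 0.5, 20, 0.4),
                                    bight_coast(coast_lon = 0.1,
                                                bight_lat = 0.5,
                                                indentation_deg = 0.2)), g)
  path <- tempfile(fileext = ".nc")
  write_currents(f, path)
  f2 <- read_currents(path)
  expect_identical(f2$u, f$u)
  expect_identical(f2$v, f$v)
  expect_identical(f2$landmask, f$landmask)
  expect_equal(as.numeric(f2$grid$times), as.numeric(g$times))
  nc <- ncdf4::nc_open(path)
  expect_identical(nc$var$uo$units, "m s-1")
  expect_identical(nc$var$vo$units, "m s-1")
  ncdf4::nc_close(nc)
})

test_that("written NetCDF is readable by an independent CF-aware reader", {
  g <- grid_spec(0, 1, 0.5, 0, 1, 0.5, daily(2))
  f <- uniform_field(0.3, -0.2, grid = g)
  path <- tempfile(fileext = ".nc")
  write_currents(f, path)
  script <- paste(
    "import xarray as xr, sys",
    sprintf("ds = xr.open_dataset('%s')", path),
    "assert ds['uo'].attrs['standard_name'] == 'eastward_sea_water_velocity'",
    "assert ds['vo'].attrs['standard_name'] == 'northward_sea_water_velocity'",
    "assert str(ds['time'].values[0]).startswith('2010-02-01')",
    "print(float(ds['uo'].isel(time=0).mean()))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(as.numeric(out[length(out)]), 0.3, tolerance = 1e-9)
})
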