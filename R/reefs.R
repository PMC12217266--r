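## Reef polygons and the seeding rule. Reefs are small (sub-km to few-km)
## convex-ish polygons tagged with a complex label; a reef_set keeps them
## ordered north -> south (the matrix axis convention) with a bounding-box
## index for containment queries.

## evaluate an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

ring_self_intersects <- function(lon, lat) {
  n <- length(lon)
  pts <- cbind(lon, lat)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      if (j == i || nxt[j] == i || nxt[i] == j) next
      if (segments_intersect(pts[i, ], pts[nxt[i], ], pts[j, ], pts[nxt[j], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' A single reef polygon
#'
#' @param reef_id unique label.
#' @param complex_id reef complex label.
#' @param lon,lat ring vertices in order (open ring: first vertex not
#'   repeated), degrees. At least 3 distinct vertices; must not
#'   self-intersect.
#' @return object of class \code{reef_polygon} with derived \code{area_km2}
#'   and centroid.
#' @export
reef_polygon <- function(reef_id, complex_id, lon, lat) {
  stop_if_not(length(lon) == length(lat) && length(lon) >= 3,
              "reef_polygon: need >= 3 vertices")
  if (lon[1] == lon[length(lon)] && lat[1] == lat[length(lat)]) {
    lon <- lon[-length(lon)]; lat <- lat[-length(lat)]
  }
  stop_if_not(nrow(unique(cbind(lon, lat))) >= 3,
              "reef_polygon: need >= 3 distinct vertices")
  if (ring_self_intersects(lon, lat)) {
    stop("reef_polygon: ring of '", reef_id, "' is self-intersecting")
  }
  p <- structure(list(reef_id = as.character(reef_id),
                      complex_id = as.character(complex_id),
                      lon = as.numeric(lon), lat = as.numeric(lat)),
                 class = "reef_polygon")
  p$centroid <- c(lon = mean(lon), lat = mean(lat))
  p$area_km2 <- area_km2(p)
  p
}

## Lambert azimuthal equal-area projection about (lon0, lat0), metres
laea_project <- function(lon, lat, lon0, lat0) {
  lam <- (lon - lon0) * pi / 180; lam0 <- 0
  phi <- lat * pi / 180; phi0 <- lat0 * pi / 180
  k <- sqrt(2 / (1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)))
  list(x = EARTH_RADIUS * k * cos(phi) * sin(lam),
       y = EARTH_RADIUS * k * (cos(phi0) * sin(phi) -
                               sin(phi0) * cos(phi) * cos(lam)))
}

#' Plan area of a reef polygon in km^2
#'
#' Shoelace area computed on a local equal-area azimuthal projection about
#' the polygon centroid; orientation independent.
#'
#' @param polygon a \code{\link{reef_polygon}} (or list with lon/lat).
#' @return area in km^2.
#' @export
area_km2 <- function(polygon) {
  lon <- polygon$lon; lat <- polygon$lat
  n <- length(lon); nxt <- c(2:n, 1)
  ## degeneracy (collinear / repeated vertices) checked in coordinate space,
  ## where projection curvature cannot inflate a zero-area ring
  if (abs(sum(lon * lat[nxt] - lon[nxt] * lat)) / 2 < 1e-12) {
    stop("area_km2: degenerate ring (zero area)")
  }
  p <- laea_project(lon, lat, mean(lon), mean(lat))
  a <- abs(sum(p$x * p$y[nxt] - p$x[nxt] * p$y)) / 2
  if (a < 1) stop("area_km2: degenerate ring (zero area)")  # < 1 m^2
  a / 1e6
}

#' Number of virtual larvae seeded on a reef
#'
#' Reefs whose plan area exceeds the threshold are seeded at a fixed density;
#' smaller reefs receive the fixed floor count. Fractional counts round to
#' the nearest integer, half away from zero.
#'
#' @param area_km2 reef plan area, km^2 (> 0).
#' @param density larvae per km^2 above the threshold (default 200).
#' @param floor count for reefs at or below the threshold (default 200).
#' @param threshold area threshold in km^2 (default 1; strict "exceeding").
#' @return integer larvae count.
#' @examples
#' seed_count(0.5)  # 200
#' seed_count(2.5)  # 500
#' @export
seed_count <- function(area_km2, density = 200, floor = 200, threshold = 1) {
  stop_if_not(all(area_km2 > 0), "seed_count: area must be positive")
  ifelse(area_km2 > threshold,
         as.integer(round_half_away(density * area_km2)),
         as.integer(round_half_away(floor)))
}

## even-odd ray casting; vectorised over query points, one polygon
point_in_polygon <- function(lon, lat, plon, plat) {
  n <- length(plon)
  inside <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- plon[i]; yi <- plat[i]; xj <- plon[j]; yj <- plat[j]
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Ordered set of reef polygons
#'
#' Validates unique ids, sorts reefs north to south by centroid latitude
#' (the connectivity-matrix axis convention) and builds a bounding-box index.
#'
#' @param polygons list of \code{\link{reef_polygon}}s.
#' @return object of class \code{reef_set}.
#' @export
reef_set <- function(polygons) {
  stop_if_not(length(polygons) >= 1, "reef_set: need at least one polygon")
  ids <- vapply(polygons, `[[`, character(1), "reef_id")
  if (anyDuplicated(ids)) {
    stop("reef_set: duplicate reef_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  clat <- vapply(polygons, function(p) p$centroid["lat"], numeric(1))
  ord <- order(clat, decreasing = TRUE)   # north -> south
  polygons <- polygons[ord]
  bbox <- t(vapply(polygons, function(p)
    c(min(p$lon), max(p$lon), min(p$lat), max(p$lat)), numeric(4)))
  colnames(bbox) <- c("lon_min", "lon_max", "lat_min", "lat_max")
  structure(list(
    polygons = polygons,
    reef_ids = vapply(polygons, `[[`, character(1), "reef_id"),
    complex_ids = vapply(polygons, `[[`, character(1), "complex_id"),
    areas_km2 = vapply(polygons, `[[`, numeric(1), "area_km2"),
    bbox = bbox
  ), class = "reef_set")
}

#' @export
print.reef_set <- function(x, ...) {
  cat(sprintf("reef_set: %d reefs in %d complexes (%s), areas %.2f-%.2f km2\n",
              length(x$polygons), length(unique(x$complex_ids)),
              paste(unique(x$complex_ids), collapse = ", "),
              min(x$areas_km2), max(x$areas_km2)))
  invisible(x)
}

#' @export
plot.reef_set <- function(x, add = FALSE, col = NULL, ...) {
  cx <- unique(x$complex_ids)
  if (is.null(col)) col <- grDevices::hcl.colors(max(2, length(cx)), "Dark 3")
  if (!add) {
    graphics::plot(NA, xlim = range(x$bbox[, 1:2]), ylim = range(x$bbox[, 3:4]),
                   xlab = "longitude", ylab = "latitude", ...)
  }
  for (i in seq_along(x$polygons)) {
    p <- x$polygons[[i]]
    graphics::polygon(p$lon, p$lat, col = col[match(p$complex_id, cx)],
                      border = NA)
  }
  invisible(x)
}

#' Which reef contains each point?
#'
#' Bounding-box index followed by even-odd containment; overlapping polygons
#' resolve to the first reef in north-to-south order.
#'
#' @param lon,lat query points, degrees (vectorised).
#' @param reefs a \code{\link{reef_set}}.
#' @return character vector of reef ids, \code{NA} where no reef contains
#'   the point.
#' @export
locate <- function(lon, lat, reefs) {
  out <- rep(NA_character_, length(lon))
  bb <- reefs$bbox
  for (k in seq_along(reefs$polygons)) {
    open <- is.na(out)
    if (!any(open)) break
    cand <- open & lon >= bb[k, 1] & lon <= bb[k, 2] &
      lat >= bb[k, 3] & lat <= bb[k, 4]
    if (!any(cand)) next
    p <- reefs$polygons[[k]]
    hit <- point_in_polygon(lon[cand], lat[cand], p$lon, p$lat)
    out[which(cand)[hit]] <- reefs$reef_ids[k]
  }
  out
}

#' Uniform release points inside a polygon
#'
#' Bounding-box rejection sampling; uniform over the polygon.
#'
#' @param polygon a \code{\link{reef_polygon}}.
#' @param n number of points (>= 1).
#' @param seed optional seed for a reproducible draw (global RNG state is
#'   restored afterwards); if \code{NULL} the current RNG stream is used.
#' @param max_tries rejection budget multiplier.
#' @return data.frame with columns lon, lat.
#' @export
sample_release_points <- function(polygon, n, seed = NULL, max_tries = 1000) {
  stop_if_not(n >= 1, "sample_release_points: n must be >= 1")
  with_seed(seed, {
    lon <- numeric(0); lat <- numeric(0)
    tries <- 0
    while (length(lon) < n && tries < max_tries) {
      m <- max(2 * (n - length(lon)), 16)
      cl <- stats::runif(m, min(polygon$lon), max(polygon$lon))
      ca <- stats::runif(m, min(polygon$lat), max(polygon$lat))
      keep <- point_in_polygon(cl, ca, polygon$lon, polygon$lat)
      lon <- c(lon, cl[keep]); lat <- c(lat, ca[keep])
      tries <- tries + 1
    }
    if (length(lon) < n) {
      stop("sample_release_points: rejection sampling failed (degenerate polygon?)")
    }
    data.frame(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
  })
}

#' Generate a synthetic reef set in alongshore bands
#'
#' Places small convex polygons (roughly 0.25-3 km^2 elliptical octagons)
#' just offshore of the coastline in latitude bands ordered north to south,
#' one band per complex. Every vertex is checked against the coastline curve
#' so polygons lie entirely in ocean. Synthetic stand-in for digitised reef
#' polygon databases.
#'
#' @param coast a \code{\link{bight_coast}}.
#' @param n_per_complex reefs per complex (>= 1).
#' @param complexes complex labels, north to south.
#' @param band_lats band centre latitudes, one per complex, strictly
#'   decreasing.
#' @param seed RNG seed (reef sets are deterministic given the seed).
#' @param offshore_deg range of eastward offsets from the coastline for reef
#'   centres, degrees.
#' @return a \code{\link{reef_set}}.
#' @export
generate_reefs <- function(coast = bight_coast(), n_per_complex = 3,
                           complexes = names(default_band_lats()),
                           band_lats = unname(default_band_lats()),
                           seed = 1, offshore_deg = c(0.10, 0.30)) {
  stop_if_not(n_per_complex >= 1, "generate_reefs: n_per_complex must be >= 1")
  stop_if_not(length(complexes) == length(band_lats),
              "generate_reefs: one band latitude per complex")
  stop_if_not(all(diff(band_lats) < 0),
              "generate_reefs: band latitudes must decrease north to south")
  with_seed(seed, {
    polys <- list()
    for (b in seq_along(complexes)) {
      ## deterministic within-band spread keeps bands non-overlapping
      offs <- seq(-0.12, 0.12, length.out = max(n_per_complex, 2))[seq_len(n_per_complex)]
      for (r in seq_len(n_per_complex)) {
        placed <- FALSE
        for (try in seq_len(200)) {
          clat <- band_lats[b] + offs[r] + stats::runif(1, -0.02, 0.02)
          clon <- coastline_lon(coast, clat) +
            stats::runif(1, offshore_deg[1], offshore_deg[2])
          a <- stats::runif(1, 0.3, 1.0); bb <- stats::runif(1, 0.3, 1.0)
          th <- stats::runif(1, 0, pi)
          ang <- seq(0, 2 * pi, length.out = 9)[-9]
          ex <- a * cos(ang); ey <- bb * sin(ang)
          xk <- ex * cos(th) - ey * sin(th); yk <- ex * sin(th) + ey * cos(th)
          vlon <- clon + xk * 1000 / m_per_deg_lon(clat)
          vlat <- clat + yk * 1000 / m_per_deg_lat()
          if (all(vlon > coastline_lon(coast, vlat) + 0.01)) {
            polys[[length(polys) + 1]] <-
              reef_polygon(sprintf("%s_%02d", complexes[b], r), complexes[b],
                           vlon, vlat)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("generate_reefs: could not place a polygon in ocean for complex ",
               complexes[b])
        }
      }
    }
    reef_set(polys)
  })
}

#' Read reef polygons from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon / MultiPolygon features
#' (lon-lat vertex order) carrying reef and complex id properties.
#' MultiPolygon parts are split into separate reefs with suffixed ids unless
#' \code{split_multipolygons = FALSE} (then only the first ring is kept).
#' Shapefile input is not supported; convert to GeoJSON first.
#'
#' @param path GeoJSON file.
#' @param id_prop,complex_prop property names for the reef and complex ids.
#' @param split_multipolygons split MultiPolygon parts into suffixed reefs?
#' @return a \code{\link{reef_set}}.
#' @export
read_reefs <- function(path, id_prop = "reef_id", complex_prop = "complex_id",
                       split_multipolygons = TRUE) {
  if (!file.exists(path)) stop("read_reefs: no such file: ", path)
  if (grepl("\\.shp$", path, ignore.case = TRUE)) {
    stop("read_reefs: ESRI shapefile input is not supported; ",
         "convert to GeoJSON (e.g. with ogr2ogr) first")
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stop_if_not(identical(gj$type, "FeatureCollection"),
              "read_reefs: expected a GeoJSON FeatureCollection")
  polys <- list()
  for (f in gj$features) {
    props <- f$properties
    rid <- props[[id_prop]]
    cid <- props[[complex_prop]]
    if (is.null(rid)) stop("read_reefs: feature missing property '", id_prop, "'")
    if (is.null(cid)) stop("read_reefs: feature missing property '",
                           complex_prop, "'")
    geom <- f$geometry
    ring_to_poly <- function(ring, id) {
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      reef_polygon(id, cid, m[, 1], m[, 2])
    }
    if (identical(geom$type, "Polygon")) {
      polys[[length(polys) + 1]] <- ring_to_poly(geom$coordinates[[1]], rid)
    } else if (identical(geom$type, "MultiPolygon")) {
      parts <- geom$coordinates
      if (split_multipolygons && length(parts) > 1) {
        for (k in seq_along(parts)) {
          polys[[length(polys) + 1]] <-
            ring_to_poly(parts[[k]][[1]], sprintf("%s_%d", rid, k))
        }
      } else {
        polys[[length(polys) + 1]] <- ring_to_poly(parts[[1]][[1]], rid)
      }
    } else {
      stop("read_reefs: unsupported geometry type: ", geom$type)
    }
  }
  reef_set(polys)
}

#' Write a reef set as GeoJSON
#'
#' @param reefs a \code{\link{reef_set}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_reefs <- function(reefs, path) {
  feats <- lapply(reefs$polygons, function(p) {
    ring <- lapply(c(seq_along(p$lon), 1),
                   function(i) c(p$lon[i], p$lat[i]))
    list(type = "Feature",
         properties = list(reef_id = p$reef_id, complex_id = p$complex_id,
                           area_km2 = p$area_km2),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Map from reef id to complex id
#'
#' @param reefs a \code{\link{reef_set}}.
#' @return named character vector.
#' @export
complex_map <- function(reefs) {
  stats::setNames(reefs$complex_ids, reefs$reef_ids)
}
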