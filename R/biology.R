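#' Larval biology windows
#'
#' A larva drifts for at most the pelagic larval duration (PLD). During the
#' initial precompetency period it cannot settle; the remainder is the
#' settlement window in which crossing a reef polygon counts as a
#' connectivity event.
#'
#' @param pld_days pelagic larval duration, days (default 10).
#' @param precompetency_days precompetency period, days (default 4; must be
#'   < pld).
#' @return object of class \code{biology_config} with derived
#'   \code{settlement_window_days}.
#' @export
biology_config <- function(pld_days = 10, precompetency_days = 4) {
  stop_if_not(precompetency_days >= 0 && precompetency_days < pld_days,
              "biology_config: need 0 <= precompetency < pld")
  structure(list(pld_days = pld_days,
                 precompetency_days = precompetency_days,
                 settlement_window_days = pld_days - precompetency_days),
            class = "biology_config")
}

#' Spawning-season release schedule
#'
#' Midnight releases every \code{interval_days} days through the spawning
#' months, anchored at the first day of the season each year (a fixed 48-h
#' stride also across a leap day).
#'
#' @param years integer vector of release years.
#' @param interval_days spacing between releases, days (default 2).
#' @param months months forming the season (default February-March).
#' @return POSIXct vector of release datetimes (UTC, 00:00).
#' @export
build_release_schedule <- function(years, interval_days = 2, months = 2:3) {
  stop_if_not(length(years) >= 1, "build_release_schedule: years is empty")
  out <- lapply(years, function(y) {
    start <- as_utc(sprintf("%04d-%02d-01", y, months[1]))
    ## generous candidate range, then keep dates inside the season
    cand <- start + 86400 * interval_days *
      (0:ceiling(62 / interval_days))
    cand[as.integer(format(cand, "%m")) %in% months &
           as.integer(format(cand, "%Y")) == y]
  })
  do.call(c, out)
}

#' Detect connectivity events along trajectories
#'
#' Scans every trajectory record whose age lies inside the settlement window
#' (precompetency <= age <= PLD) and whose status is ACTIVE, locating the
#' position against the reef polygons. The first containment per (particle,
#' destination reef) pair emits one event with travel time equal to the age
#' at that record; larvae are not removed after settling and may connect to
#' multiple destinations. Arrival at the source reef itself is recorded as
#' self-recruitment. Stranded records are not containment-tested (reefs are
#' subtidal).
#'
#' @param traj a \code{trajectory_set}.
#' @param reefs a \code{\link{reef_set}}.
#' @param bio a \code{\link{biology_config}}.
#' @return data.frame of events: particle_id, source_reef, dest_reef,
#'   release_time, arrival_time, travel_time_h.
#' @export
detect_events <- function(traj, reefs, bio = biology_config()) {
  if (traj$config$dt > 1800 * 1.0001) {
    warning("detect_events: trajectory step coarser than 30 min; ",
            "fast crossings may be missed")
  }
  pre_s <- bio$precompetency_days * 86400
  pld_s <- bio$pld_days * 86400
  evs <- list()
  for (b in traj$batches) {
    n <- nrow(b$lon)
    ages <- b$times - b$times[1]
    cols <- which(ages >= pre_s & ages <= pld_s)
    seen <- matrix(FALSE, n, length(reefs$reef_ids))
    for (cc in cols) {
      act <- which(b$status[, cc] == ST_ACTIVE)
      if (length(act) == 0) next
      hit <- locate(b$lon[act, cc], b$lat[act, cc], reefs)
      got <- !is.na(hit)
      if (!any(got)) next
      pk <- act[got]
      rk <- match(hit[got], reefs$reef_ids)
      new <- !seen[cbind(pk, rk)]
      if (!any(new)) next
      pk <- pk[new]; rk <- rk[new]
      seen[cbind(pk, rk)] <- TRUE
      evs[[length(evs) + 1]] <- data.frame(
        particle_id = b$particle_id[pk],
        source_reef = b$source_reef[pk],
        dest_reef = reefs$reef_ids[rk],
        release_time = rep(b$release_time, length(pk)),
        arrival_time = as.POSIXct(b$times[cc], origin = "1970-01-01",
                                  tz = "UTC"),
        travel_time_h = rep(ages[cc] / 3600, length(pk)))
    }
  }
  if (length(evs) == 0) {
    return(data.frame(particle_id = character(), source_reef = character(),
                      dest_reef = character(),
                      release_time = as_utc(character()),
                      arrival_time = as_utc(character()),
                      travel_time_h = numeric()))
  }
  do.call(rbind, evs)
}

#' Build the source-by-destination connectivity matrix
#'
#' counts[i, j] is the number of distinct larvae released at source reef i
#' that reached destination reef j, accumulated over all releases. The
#' diagonal is self-recruitment. Reefs are ordered north to south on both
#' axes.
#'
#' @param events event data.frame from \code{\link{detect_events}}.
#' @param reefs a \code{\link{reef_set}}.
#' @param released named vector of larvae released per source reef.
#' @return object of class \code{connectivity_matrix}.
#' @export
build_matrix <- function(events, reefs, released) {
  ids <- reefs$reef_ids
  stop_if_not(all(ids %in% names(released)),
              "build_matrix: released counts missing for some reefs")
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(c(events$source_reef, events$dest_reef)), ids)
    if (length(unknown) > 0) {
      stop("build_matrix: events reference unknown reefs: ",
           paste(unknown, collapse = ", "))
    }
    events <- events[!duplicated(events[c("particle_id", "dest_reef")]), ]
  }
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(events) > 0) {
    tab <- table(factor(events$source_reef, levels = ids),
                 factor(events$dest_reef, levels = ids))
    counts <- counts + unclass(tab)
  }
  structure(list(counts = counts,
                 released = released[ids],
                 reef_ids = ids,
                 complex_ids = reefs$complex_ids),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d reefs, %d events, self-recruitment %d\n",
              length(x$reef_ids), sum(x$counts), sum(diag(x$counts))))
  invisible(x)
}

#' @export
plot.connectivity_matrix <- function(x, log = TRUE, ...) {
  m <- x$counts
  z <- if (log) log10(1 + m) else m
  n <- nrow(m)
  ## source i on rows top->bottom, destination j on columns left->right
  graphics::image(seq_len(n), seq_len(n), t(z[n:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "destination reef (N to S)",
                  ylab = "source reef (S to N)", axes = FALSE, ...)
  graphics::box()
  breaks <- which(diff(as.integer(factor(x$complex_ids,
                                         levels = unique(x$complex_ids)))) != 0)
  graphics::abline(v = breaks + 0.5, h = n - breaks + 0.5, col = "black")
  invisible(x)
}

#' Mean and standard-deviation travel-time matrices
#'
#' Per source/destination pair the arithmetic mean and the population
#' standard deviation of event travel times, in hours; cells with no events
#' are empty (NA), exactly where the connectivity matrix is zero.
#'
#' @param events event data.frame.
#' @param reefs a \code{\link{reef_set}}.
#' @return object of class \code{travel_time_stats} with matrices
#'   \code{mean_h}, \code{sd_h}, \code{n}.
#' @export
travel_time_stats <- function(events, reefs) {
  ids <- reefs$reef_ids
  k <- length(ids)
  mean_h <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  sd_h <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  nm <- matrix(0L, k, k, dimnames = list(ids, ids))
  if (nrow(events) > 0) {
    si <- match(events$source_reef, ids)
    di <- match(events$dest_reef, ids)
    grp <- (si - 1L) * k + di
    sums <- rowsum(events$travel_time_h, grp)
    sqs <- rowsum(events$travel_time_h^2, grp)
    cnt <- rowsum(rep(1L, nrow(events)), grp)
    g <- as.integer(rownames(sums))
    ii <- ((g - 1L) %/% k) + 1L   # source
    jj <- ((g - 1L) %% k) + 1L    # destination
    mu <- sums[, 1] / cnt[, 1]
    va <- pmax(sqs[, 1] / cnt[, 1] - mu^2, 0)   # population variance
    mean_h[cbind(ii, jj)] <- mu
    sd_h[cbind(ii, jj)] <- sqrt(va)
    nm[cbind(ii, jj)] <- cnt[, 1]
  }
  structure(list(mean_h = mean_h, sd_h = sd_h, n = nm, reef_ids = ids),
            class = "travel_time_stats")
}

#' @export
print.travel_time_stats <- function(x, ...) {
  cat(sprintf("travel_time_stats: %d connected pairs, mean travel time %.1f h\n",
              sum(x$n > 0),
              mean(x$mean_h[x$n > 0])))
  invisible(x)
}

#' Aggregate a reef-level matrix to reef complexes
#'
#' Block sums of the counts by (source complex, destination complex);
#' complexes keep their north-to-south order.
#'
#' @param matrix a \code{\link{build_matrix}} result.
#' @param cmap named character vector reef_id -> complex_id (default the
#'   matrix's own complex labels).
#' @return a \code{connectivity_matrix} at complex level.
#' @export
aggregate_complexes <- function(matrix, cmap = NULL) {
  x <- matrix
  cm <- cmap %||% stats::setNames(x$complex_ids, x$reef_ids)
  if (!all(x$reef_ids %in% names(cm))) {
    stop("aggregate_complexes: unmapped reefs: ",
         paste(setdiff(x$reef_ids, names(cm)), collapse = ", "))
  }
  cx <- cm[x$reef_ids]
  lev <- unique(cx)
  f <- factor(cx, levels = lev)
  blocks <- rowsum(t(rowsum(x$counts, f, reorder = FALSE)), f, reorder = FALSE)
  blocks <- t(blocks)
  rel <- as.vector(rowsum(as.numeric(x$released), f, reorder = FALSE))
  structure(list(counts = blocks,
                 released = stats::setNames(rel, lev),
                 reef_ids = lev, complex_ids = lev),
            class = "connectivity_matrix")
}

#' Larvae received by a destination complex over time
#'
#' Counts connectivity events whose destination reef lies in the target
#' complex, grouped by release year or by individual release, split by
#' source complex. Events whose source complex equals the destination
#' complex are excluded, to emphasise the contribution of neighbouring
#' complexes.
#'
#' @param events event data.frame.
#' @param destination_complex complex label of the destination.
#' @param cmap named character vector reef_id -> complex_id.
#' @param group_by "year" or "release".
#' @return data.frame with columns group, source_complex, count.
#' @export
temporal_contributions <- function(events, destination_complex, cmap,
                                   group_by = c("year", "release")) {
  group_by <- match.arg(group_by)
  known <- unique(cmap)
  if (!destination_complex %in% known) {
    stop("temporal_contributions: unknown complex '", destination_complex, "'")
  }
  if (nrow(events) > 0) {
    miss <- setdiff(unique(c(events$source_reef, events$dest_reef)), names(cmap))
    if (length(miss) > 0) {
      stop("temporal_contributions: reefs not in complex map: ",
           paste(miss, collapse = ", "))
    }
  }
  sel <- events[cmap[events$dest_reef] == destination_complex &
                  cmap[events$source_reef] != destination_complex, ,
                drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(group = character(), source_complex = character(),
                      count = integer()))
  }
  grp <- if (group_by == "year") format(sel$release_time, "%Y") else
    format(sel$release_time, "%Y-%m-%d")
  agg <- stats::aggregate(list(count = rep(1L, nrow(sel))),
                          by = list(group = grp,
                                    source_complex = unname(cmap[sel$source_reef])),
                          FUN = sum)
  agg[order(agg$group, agg$source_complex), , drop = FALSE]
}
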