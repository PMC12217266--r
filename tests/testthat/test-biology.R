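## hand-built trajectory: one batch, half-day records over 10 days
fake_traj <- function(lon, lat, status = NULL, dt_rec = 43200,
                      cfg = tracker_config()) {
  n_rec <- ncol(lon)
  structure(list(
    batches = list(list(
      release_time = t0,
      times = as.numeric(t0) + dt_rec * (seq_len(n_rec) - 1),
      lon = lon, lat = lat,
      status = status %||% matrix(0L, nrow(lon), n_rec),
      particle_id = sprintf("p%d", seq_len(nrow(lon))),
      source_reef = rep("src", nrow(lon)))),
    config = cfg), class = "trajectory_set")
}

two_reefs <- function() {
  reef_set(list(axis_square("j", "X", 1, 0, 0.05),
                axis_square("k", "X", 2, -1, 0.05)))
}

test_that("events respect the precompetency window and first-contact rule", {
  reefs <- two_reefs()
  ## records every 12 h: ages 0, 0.5, ..., 10 d (21 records)
  path <- rep(10, 21)   # far from any reef
  ## particle 1: inside reef j only at age 3.5 d (record 8) -> no event
  lon1 <- path; lon1[8] <- 1; lat1 <- path * 0; lat1[8] <- 0
  ## particle 2: enters reef j at age 5 d (record 11), stays two records,
  ## later crosses reef k at 8 d (record 17), re-enters j at 9 d -> 2 events
  lon2 <- path; lat2 <- path * 0
  lon2[11:12] <- 1; lon2[17] <- 2; lat2[17] <- -1; lon2[19] <- 1
  lon <- rbind(lon1, lon2); lat <- rbind(lat1, lat2)
  ev <- detect_events(fake_traj(lon, lat), reefs, biology_config())
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$particle_id, c("p2", "p2"))
  expect_setequal(ev$dest_reef, c("j", "k"))
  expect_equal(ev$travel_time_h[ev$dest_reef == "j"], 120)  # age 5 d
  expect_equal(ev$travel_time_h[ev$dest_reef == "k"], 192)
  ## matches the independent brute-force re-scan
  orc <- oracle_events(fake_traj(lon, lat), reefs)
  expect_equal(nrow(orc), 2L)
  expect_setequal(orc$dest_reef, ev$dest_reef)
  expect_equal(sort(orc$travel_time_h), sort(ev$travel_time_h))
})

test_that("stranded and inactive records do not settle; window bounds hold", {
  reefs <- two_reefs()
  lon <- matrix(1, 1, 21); lat <- matrix(0, 1, 21)   # parked on reef j
  st <- matrix(0L, 1, 21); st[1, ] <- 1L             # but stranded throughout
  ev <- detect_events(fake_traj(lon, lat, st), reefs)
  expect_identical(nrow(ev), 0L)
  ## active particle parked on its reef settles at the first competent record
  ev2 <- detect_events(fake_traj(matrix(1, 1, 21), matrix(0, 1, 21)), reefs)
  expect_identical(nrow(ev2), 1L)
  expect_equal(ev2$travel_time_h, 96)   # exactly the precompetency bound
  b <- biology_config()
  expect_true(all(ev2$travel_time_h >= b$precompetency_days * 24 &
                  ev2$travel_time_h <= b$pld_days * 24))
  expect_error(biology_config(10, 10), "precompetency")
  expect_identical(biology_config()$settlement_window_days, 6)
})

test_that("a coarse trajectory step warns about missed crossings", {
  lon <- matrix(10, 1, 5); lat <- matrix(0, 1, 5)
  tr <- fake_traj(lon, lat, cfg = tracker_config(dt = 7200))
  expect_warning(detect_events(tr, two_reefs()), "coarser")
})

test_that("matrix building counts distinct larvae and checks its inputs", {
  reefs <- two_reefs()
  released <- c(j = 10, k = 10)
  empty <- detect_events(fake_traj(matrix(10, 1, 21), matrix(0, 1, 21)), reefs)
  m0 <- build_matrix(empty, reefs, released)
  expect_true(all(m0$counts == 0))

  ev <- data.frame(particle_id = c("a", "b", "c", "c"),
                   source_reef = "j", dest_reef = c("k", "k", "k", "k"),
                   release_time = t0, arrival_time = t0 + 5 * 86400,
                   travel_time_h = 120)
  m <- build_matrix(ev, reefs, released)
  expect_identical(m$counts["j", "k"], 3L)   # duplicate (c, k) collapses
  expect_true(all(m$counts <= m$released[row(m$counts)]))
  bad <- ev; bad$dest_reef[1] <- "nope"
  expect_error(build_matrix(bad, reefs, released), "unknown reefs")

  ## random event tables match an independent tally
  set.seed(14)
  ids <- c("j", "k")
  rev <- data.frame(particle_id = sprintf("p%d", sample(50, 200, TRUE)),
                    source_reef = sample(ids, 200, TRUE),
                    dest_reef = sample(ids, 200, TRUE),
                    release_time = t0, arrival_time = t0,
                    travel_time_h = runif(200, 96, 240))
  m <- build_matrix(rev, reefs, c(j = 1000, k = 1000))
  dedup <- rev[!duplicated(rev[c("particle_id", "dest_reef")]), ]
  for (s in ids) for (d in ids) {
    expect_identical(m$counts[s, d],
                     sum(dedup$source_reef == s & dedup$dest_reef == d))
  }
})

test_that("travel-time statistics use the population standard deviation", {
  reefs <- two_reefs()
  one <- data.frame(particle_id = "a", source_reef = "j", dest_reef = "k",
                    release_time = t0, arrival_time = t0,
                    travel_time_h = 120)
  s1 <- travel_time_stats(one, reefs)
  expect_equal(s1$mean_h["j", "k"], 120)
  expect_equal(s1$sd_h["j", "k"], 0)
  two <- rbind(one, one); two$particle_id <- c("a", "b")
  two$travel_time_h <- c(96, 144)
  s2 <- travel_time_stats(two, reefs)
  expect_equal(s2$mean_h["j", "k"], 120)
  expect_equal(s2$sd_h["j", "k"], 24)

  set.seed(5)
  rnd <- data.frame(particle_id = sprintf("p%d", 1:300),
                    source_reef = sample(c("j", "k"), 300, TRUE),
                    dest_reef = sample(c("j", "k"), 300, TRUE),
                    release_time = t0, arrival_time = t0,
                    travel_time_h = runif(300, 96, 240))
  st <- travel_time_stats(rnd, reefs)
  mm <- build_matrix(rnd, reefs, c(j = 1e4, k = 1e4))
  for (s in c("j", "k")) for (d in c("j", "k")) {
    x <- rnd$travel_time_h[rnd$source_reef == s & rnd$dest_reef == d]
    ## two-pass reference: mean then population sd
    expect_equal(st$mean_h[s, d], mean(x), tolerance = 1e-9)
    expect_equal(st$sd_h[s, d], sqrt(mean((x - mean(x))^2)), tolerance = 1e-9)
    ## emptiness matches zero connectivity (counts deduplicate particles,
    ## so compare presence only)
    expect_identical(st$n[s, d] > 0, mm$counts[s, d] > 0)
  }
})

test_that("complex aggregation block-sums the reef matrix", {
  polys <- list(axis_square("a1", "A", 0, 0, 0.01),
                axis_square("a2", "A", 0.5, -0.1, 0.01),
                axis_square("b1", "B", 0, -1, 0.01),
                axis_square("b2", "B", 0.5, -1.1, 0.01))
  reefs <- reef_set(polys)
  ids <- reefs$reef_ids
  ev <- expand.grid(source_reef = ids, dest_reef = ids,
                    stringsAsFactors = FALSE)
  ev$particle_id <- sprintf("p%d", seq_len(nrow(ev)))
  ev$release_time <- t0; ev$arrival_time <- t0; ev$travel_time_h <- 120
  m <- build_matrix(ev, reefs, setNames(rep(100, 4), ids))
  cm <- aggregate_complexes(m)
  expect_identical(dim(cm$counts), c(2L, 2L))
  expect_true(all(cm$counts == 4))   # every block sums 2 x 2 ones
  ## identity map leaves the matrix unchanged
  idm <- aggregate_complexes(m, setNames(ids, ids))
  expect_equal(unname(idm$counts), unname(m$counts))
  ## brute-force block sums
  cmap <- complex_map(reefs)
  for (s in c("A", "B")) for (d in c("A", "B")) {
    expect_identical(cm$counts[s, d],
                     sum(m$counts[cmap[ids] == s, cmap[ids] == d]))
  }
  expect_error(aggregate_complexes(m, c(a1 = "A")), "unmapped")
})

test_that("temporal contributions exclude the destination complex itself", {
  cmap <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  mk <- function(src, dst, when) {
    data.frame(particle_id = paste0(src, dst, when), source_reef = src,
               dest_reef = dst, release_time = as.POSIXct(when, tz = "UTC"),
               arrival_time = as.POSIXct(when, tz = "UTC") + 5 * 86400,
               travel_time_h = 120)
  }
  ## all intra-complex -> empty table
  intra <- rbind(mk("a1", "a2", "2010-02-01"), mk("a2", "a1", "2010-02-03"))
  expect_identical(nrow(temporal_contributions(intra, "A", cmap)), 0L)

  ev <- rbind(mk("b1", "a1", "2010-02-01"), mk("c1", "a2", "2010-02-05"),
              mk("b1", "a2", "2011-02-01"), mk("a1", "a2", "2010-02-01"))
  tc <- temporal_contributions(ev, "A", cmap, "year")
  expect_identical(sum(tc$count), 3L)          # intra-A event dropped
  expect_setequal(tc$source_complex[tc$group == "2010"], c("B", "C"))
  ## grouping by release then summing per year equals the yearly grouping
  tr <- temporal_contributions(ev, "A", cmap, "release")
  byyear <- aggregate(count ~ source_complex + substr(group, 1, 4), tr, sum)
  names(byyear)[2] <- "group"
  m1 <- byyear[order(byyear$group, byyear$source_complex),
               c("group", "source_complex", "count")]
  m2 <- tc[order(tc$group, tc$source_complex),
           c("group", "source_complex", "count")]
  expect_equal(unname(as.matrix(m1)), unname(as.matrix(m2)))
  expect_error(temporal_contributions(ev, "Z", cmap), "unknown complex")
})

test_that("the release schedule covers the season at 48-hour stride", {
  s2010 <- build_release_schedule(2010)    # non-leap February
  ## independent enumeration: every second day of Feb-Mar
  days <- seq(as.Date("2010-02-01"), as.Date("2010-03-31"), by = "2 days")
  expect_identical(length(s2010), length(days))  # 30 releases
  expect_identical(as.Date(s2010, tz = "UTC"), days)
  expect_identical(format(s2010[1], "%Y-%m-%d %H:%M"), "2010-02-01 00:00")
  expect_identical(format(s2010[30], "%Y-%m-%d %H:%M"), "2010-03-31 00:00")
  expect_true(all(format(s2010, "%H%M%S") == "000000"))   # midnight spawn

  s2012 <- build_release_schedule(2012)    # leap year
  expect_true(all(diff(as.numeric(s2012)) == 2 * 86400))
  expect_true(all(as.integer(format(s2012, "%m")) %in% 2:3))
  expect_identical(length(s2012), 30L)

  s_all <- build_release_schedule(1994:2014)
  expect_identical(length(s_all), 21L * 30L)
})
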