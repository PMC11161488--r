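mk_det <- function(stamps, stations, tag = "t1",
                   st_tab = data.frame(
                     station_id = c("a1", "a2", "b1"),
                     lat = c(51, 51.05, 51.5), lon = c(2, 2.05, 3),
                     array = c("A", "A", "B"))) {
  detection_set(st_tab, data.frame(
    tag_id = tag, timestamp = as.POSIXct(stamps, tz = "UTC"),
    station_id = stations))
}

test_that("percentage formatter rounds to one decimal", {
  expect_equal(pct(102, 136), 75.0)
  expect_equal(pct(22, 136), 16.2)
  expect_equal(pct(1, 3), 33.3)
  expect_error(pct(1, 0))
})

test_that("detection positive days count distinct calendar days in scope", {
  det <- mk_det(c("2015-06-01 01:00", "2015-06-01 02:00",
                  "2015-06-01 03:00", "2015-06-03 01:00"),
                c("a1", "a1", "a2", "b1"))
  expect_equal(detection_positive_days(det, "t1"), 2L)
  expect_equal(detection_positive_days(det, "t1", c("a1", "a2")), 1L)
  expect_equal(detection_positive_days(det, "ghost"), 0L)
  # area subset never exceeds the full station set
  expect_lte(detection_positive_days(det, "t1", "a1"),
             detection_positive_days(det, "t1"))
})

test_that("residency index is DPD over time at large", {
  expect_equal(residency_index(10, 100), 0.10)
  expect_equal(residency_index(50, 50), 1.0)
  expect_error(residency_index(1, 0), "time_at_large")
  # recapture before battery end shortens the denominator
  t1 <- time_at_large("2015-06-01", battery_end = "2016-06-01")
  t2 <- time_at_large("2015-06-01", battery_end = "2016-06-01",
                      recapture_date = "2015-09-01")
  expect_gt(residency_index(30, t2), residency_index(30, t1))
  expect_false(attr(time_at_large("2015-06-01",
                                  last_observation = "2015-09-01"),
                    "battery_known"))
})

test_that("fidelity requires an observation at or beyond the horizon", {
  tagging <- as.Date("2015-06-01")
  expect_true(fidelity(tagging + 200, tagging))
  expect_false(fidelity(tagging + c(10, 100, 179), tagging))
  expect_true(fidelity(tagging + c(10, 300), tagging))   # recapture day 300
  expect_false(fidelity(as.Date(character(0)), tagging))
  # monotone: adding observations never cancels fidelity
  expect_true(fidelity(tagging + c(10, 100, 179, 200), tagging))
})

test_that("recapture statistics bin displacements with left-closed edges", {
  rec <- recapture_records(data.frame(
    tag_id = c("r1", "r2", "r3", "r4"),
    release_date = "2015-06-01", release_lat = 51, release_lon = 2,
    recapture_date = "2015-07-01",
    recapture_lat = c(51, 51.02, 51.6, 53.0),
    recapture_lon = c(2, 2, 2, 2)))
  # distances: 0, ~2.2, ~66.7, ~222 km
  rs <- recapture_stats(rec)
  expect_equal(unname(rs$bins), c(2L, 1L, 1L))
  expect_equal(rs$n_excluded, 0L)
  rec$recapture_lat[2] <- NA
  rs2 <- recapture_stats(rec)
  expect_equal(rs2$n_excluded, 1L)
  expect_equal(sum(rs2$bins), 3L)
})

mk_track <- function(vit, mean_pos = vit, modal_pos = vit,
                     dates = as.Date("2015-06-01") + seq_len(nrow(vit)) - 1) {
  tr <- structure(list(
    tag_id = "t1", dates = dates,
    viterbi = data.frame(date = dates, lat = vit$lat, lon = vit$lon),
    mean = data.frame(date = dates, lat = mean_pos$lat, lon = mean_pos$lon),
    modal = data.frame(date = dates, lat = modal_pos$lat,
                       lon = modal_pos$lon),
    loglik = 0, D = 10, D_low = NA_real_, D_high = NA_real_,
    reliability = NA_character_, err = NULL), class = "posterior_track")
  validate_track(tr)
}

areas4 <- area_set(list(
  "North Sea" = list(lon = c(-3, 4, 4, -3), lat = c(52, 52, 55, 55)),
  "English Channel" = list(lon = c(-3, 4, 4, -3), lat = c(50, 50, 52, 52)),
  "Celtic Sea" = list(lon = c(-3, 4, 4, -3), lat = c(49, 49, 50, 50)),
  "Bay of Biscay" = list(lon = c(-3, 4, 4, -3), lat = c(45, 45, 49, 49))),
  check_overlap = FALSE)

test_that("area assignment follows the Viterbi/mode/mean agreement rule", {
  vit <- data.frame(lat = rep(53, 3), lon = rep(2, 3))
  at <- assign_areas(mk_track(vit), areas4)
  expect_equal(at$area, rep("North Sea", 3))
  # mean in another area on day 2: unknown
  mean_pos <- vit; mean_pos$lat[2] <- 51
  at2 <- assign_areas(mk_track(vit, mean_pos = mean_pos), areas4)
  expect_equal(at2$area, c("North Sea", "unknown", "North Sea"))
  # cooling-water flag overrides
  at3 <- assign_areas(mk_track(vit), areas4,
                      cooling_flags = c(FALSE, TRUE, FALSE))
  expect_equal(at3$area[2], "cooling waters")
  # unreliable tracks are refused
  far <- vit; far$lat[2] <- 45
  tr_bad <- mk_track(vit, mean_pos = far)
  expect_equal(tr_bad$reliability, "unreliable")
  expect_error(assign_areas(tr_bad, areas4), "unreliable")
})

test_that("strategy classification picks the most distal persistent area", {
  mk_at <- function(lab, lon = rep(2, length(lab))) {
    structure(data.frame(
      date = as.Date("2015-06-01") + seq_along(lab) - 1, area = lab,
      lat = 51, lon = lon), class = c("area_track", "data.frame"))
  }
  ns <- mk_at(rep("North Sea", 100))
  expect_equal(classify_strategy(ns), "North Sea")
  # short series are unclassified
  expect_equal(classify_strategy(mk_at(rep("North Sea", 90))),
               "unclassified")
  # 10 Celtic Sea days dominate the ordering
  mixed <- mk_at(c(rep("North Sea", 80), rep("Celtic Sea", 10),
                   rep("North Sea", 10)))
  expect_equal(classify_strategy(mixed), "Celtic Sea-Bay of Biscay")
  # two stray EC days (< 5) do not count
  stray <- mk_at(c(rep("North Sea", 95), rep("English Channel", 2),
                   rep("North Sea", 8)), lon = rep(2, 105))
  expect_equal(classify_strategy(stray), "North Sea")
  # the east/west channel split at 1 degree W
  west <- mk_at(c(rep("North Sea", 85), rep("English Channel", 10)),
                lon = c(rep(2, 85), rep(-2, 10)))
  expect_equal(classify_strategy(west), "English Channel W")
  east <- mk_at(c(rep("North Sea", 85), rep("English Channel", 10)),
                lon = c(rep(2, 85), rep(0, 10)))
  expect_equal(classify_strategy(east), "English Channel E")
})

test_that("strategy summary reports distance arithmetic and group medians", {
  # 100 daily hops of ~10 km straight north
  lat <- 51 + (0:100) * (10 / 111.19)
  vit <- data.frame(lat = lat, lon = rep(2, 101))
  tr <- mk_track(vit)
  out <- strategy_summary(list(tr), "North Sea")
  expect_equal(out$distance_km_median, 1000, tolerance = 1e-3)
  expect_equal(out$n, 1L)
  # stationary track has zero distance
  tr0 <- mk_track(data.frame(lat = rep(51, 5), lon = rep(2, 5)))
  out0 <- strategy_summary(list(tr0), "North Sea")
  expect_equal(out0$distance_km_median, 0)
  # group median equals direct recomputation
  trs <- list(tr, tr0, tr)
  outg <- strategy_summary(trs, rep("North Sea", 3))
  dists <- vapply(trs, function(t) {
    v <- t$viterbi
    sum(haversine_km(v$lat[-nrow(v)], v$lon[-nrow(v)],
                     v$lat[-1], v$lon[-1]))
  }, numeric(1))
  expect_equal(outg$distance_km_median, stats::median(dists))
})

test_that("movement networks count animals and directed transitions", {
  st <- data.frame(station_id = c("a1", "a2", "b1"),
                   lat = c(51, 51.05, 51.5), lon = c(2, 2.05, 3),
                   array = c("A", "A", "B"))
  groups <- c(a1 = "G_A", a2 = "G_A", b1 = "G_B")
  det <- mk_det(c("2015-06-01 01:00", "2015-06-02 01:00",
                  "2015-06-03 01:00"), c("a1", "b1", "a2"), st_tab = st)
  net <- build_network(det, groups)
  expect_equal(sort(net$nodes$group), c("G_A", "G_B"))
  expect_equal(net$nodes$n_animals, c(1L, 1L))
  expect_equal(sum(net$edges$count), 2L)        # A->B and B->A
  # detections within one group only: one node, no edges
  det1 <- mk_det(c("2015-06-01 01:00", "2015-06-02 01:00"),
                 c("a1", "a2"), st_tab = st)
  net1 <- build_network(det1, groups)
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(nrow(net1$edges), 0L)
  # unknown stations are rejected
  expect_error(build_network(det, groups[-1]), "grouping map")
})

test_that("network construction is independent of input row order", {
  st <- data.frame(station_id = sprintf("s%d", 1:4),
                   lat = c(51, 51.2, 51.4, 51.6), lon = 2:5 / 2,
                   array = rep("A", 4))
  groups <- stats::setNames(c("G1", "G1", "G2", "G3"), st$station_id)
  set.seed(55)
  de <- data.frame(
    tag_id = sample(c("t1", "t2"), 30, replace = TRUE),
    timestamp = as.POSIXct("2015-06-01", tz = "UTC") +
      sample.int(3e6, 30),
    station_id = sample(st$station_id, 30, replace = TRUE))
  n1 <- build_network(detection_set(st, de), groups)
  shuf <- de[sample.int(nrow(de)), ]
  n2 <- build_network(detection_set(st, shuf), groups)
  o1 <- n1$edges[do.call(order, n1$edges[c("from", "to", "season")]), ]
  o2 <- n2$edges[do.call(order, n2$edges[c("from", "to", "season")]), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(n1$nodes[order(n1$nodes$group), ],
               n2$nodes[order(n2$nodes$group), ], ignore_attr = TRUE)
})

test_that("cohort-level percentage summaries match truth-label recomputation", {
  # synthetic cohort of 40 tags with known recapture outcomes: the pipeline
  # summary (pct of bins) must equal direct recomputation from truth
  set.seed(56)
  n <- 40
  d_km <- c(stats::runif(20, 0, 4), stats::runif(12, 6, 90),
            stats::runif(8, 120, 400))
  lat0 <- rep(51, n)
  rec <- recapture_records(data.frame(
    tag_id = sprintf("c%02d", 1:n), release_date = "2015-06-01",
    release_lat = lat0, release_lon = 2,
    recapture_date = "2015-09-01",
    recapture_lat = lat0 + d_km / 111.19, recapture_lon = 2))
  rs <- recapture_stats(rec)
  expect_equal(unname(rs$bins), c(20L, 12L, 8L))
  expect_equal(pct(rs$bins[[1]], n), pct(20, 40))
  expect_equal(pct(rs$bins[[1]], n), 50.0)
})
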