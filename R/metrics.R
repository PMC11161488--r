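# Movement-ecology summaries: detection positive days, residency index,
# site fidelity, recapture statistics, area assignment, migration-strategy
# classification and seasonal movement networks.

#' Percentage formatter
#'
#' `100 * count / total`, rounded to one decimal -- the convention used in
#' all percentage summaries this package prints.
#'
#' @param count,total Numerator and denominator.
#' @return Numeric percentage, one decimal.
#' @export
pct <- function(count, total) {
  stopifnot(total > 0)
  round(100 * count / total, 1)
}

#' Detection positive days
#'
#' A day counts when the tag was detected at least once at a station in
#' the area of interest.
#'
#' @param det A QC'd [detection_set()].
#' @param tag_id Tag identifier.
#' @param station_ids Stations defining the area (default: all stations).
#' @return Integer count of distinct detection days.
#' @export
detection_positive_days <- function(det, tag_id,
                                    station_ids = det$stations$station_id) {
  d <- det$detections
  sel <- d$tag_id == tag_id & d$station_id %in% station_ids
  length(unique(as.Date(d$timestamp[sel], tz = "UTC")))
}

#' Residency index
#'
#' Detection positive days out of the time at large (tagging to the end of
#' the battery lifetime, or to recapture if that came first).
#'
#' @param dpd Detection-positive-day count.
#' @param time_at_large Days at large (>= 1).
#' @return RI in [0, 1].
#' @export
residency_index <- function(dpd, time_at_large) {
  if (time_at_large <= 0) stop("residency_index: time_at_large must be >= 1")
  ri <- dpd / time_at_large
  stopifnot(ri >= 0, ri <= 1 + 1e-9)
  min(ri, 1)
}

#' Time at large
#'
#' Days from tagging to the earlier of battery end and recapture. When the
#' battery end is unknown, the last observation date substitutes for it
#' (flagged via the `battery_known` attribute).
#'
#' @param tagging_date Date of tagging.
#' @param battery_end Date the battery died, or `NA`.
#' @param recapture_date Date of recapture, or `NA`.
#' @param last_observation Fallback end date when the battery end is
#'   unknown.
#' @return Integer days, with attribute `battery_known`.
#' @export
time_at_large <- function(tagging_date, battery_end = NA,
                          recapture_date = NA, last_observation = NA) {
  tagging_date <- as.Date(tagging_date)
  end <- if (!is.na(battery_end)) as.Date(battery_end)
         else as.Date(last_observation)
  if (is.na(end)) stop("time_at_large: need battery_end or last_observation")
  if (!is.na(recapture_date)) end <- min(end, as.Date(recapture_date))
  structure(as.integer(end - tagging_date),
            battery_known = !is.na(battery_end))
}

#' Site fidelity
#'
#' A fish exhibits fidelity to an area when it was observed there (by
#' recapture, acoustic detection or reconstructed trajectory) at least
#' `horizon` days after tagging. Adding observations can only turn
#' fidelity on, never off.
#'
#' @param obs_dates Dates of qualifying observations in the area.
#' @param tagging_date Date of tagging.
#' @param horizon Days after tagging (default 180).
#' @return Logical.
#' @export
fidelity <- function(obs_dates, tagging_date, horizon = 180) {
  if (length(obs_dates) == 0) return(FALSE)
  any(as.numeric(as.Date(obs_dates) - as.Date(tagging_date)) >= horizon)
}

#' Recapture displacement statistics
#'
#' Haversine displacement and integer days at large per record, plus
#' counts in the distance bins `[0, 5)`, `[5, 100)`, `[100, Inf)` km.
#'
#' @param records A [recapture_records()] data frame.
#' @return List: `records` (with distance/days), `bins` (named counts),
#'   `n_excluded` (records missing a position).
#' @export
recapture_stats <- function(records) {
  pos_ok <- stats::complete.cases(
    as.data.frame(records)[, c("release_lat", "release_lon",
                               "recapture_lat", "recapture_lon")])
  r <- records[pos_ok, , drop = FALSE]
  bins <- c("<5 km" = sum(r$distance_km < 5),
            "5-100 km" = sum(r$distance_km >= 5 & r$distance_km < 100),
            ">100 km" = sum(r$distance_km >= 100))
  list(records = r, bins = bins, n_excluded = sum(!pos_ok))
}

#' Assign daily areas to a reconstructed track
#'
#' The daily label comes from the Viterbi position's polygon; when the
#' modal or mean position of the same day falls in a different polygon the
#' label is downgraded to `"unknown"`, and cooling-water flagged days are
#' labelled `"cooling waters"`.
#'
#' @param track A validated `posterior_track` (tier `reliable` or
#'   `temporal_only`).
#' @param areas An [area_set()].
#' @param cooling_flags Optional logical vector (per day) of cooling-water
#'   flags from preprocessing.
#' @return Object of class `area_track`: data frame `date, area, lat,
#'   lon` (Viterbi coordinates).
#' @export
assign_areas <- function(track, areas, cooling_flags = NULL) {
  stopifnot(inherits(track, "posterior_track"))
  if (identical(track$reliability, "unreliable")) {
    stop("assign_areas: track is unreliable; not assignable")
  }
  a_vit <- locate_area(track$viterbi$lat, track$viterbi$lon, areas)
  a_mod <- locate_area(track$modal$lat, track$modal$lon, areas)
  a_mean <- locate_area(track$mean$lat, track$mean$lon, areas)
  lab <- a_vit
  disagree <- !is.na(a_vit) &
    ((!is.na(a_mod) & a_mod != a_vit) | (!is.na(a_mean) & a_mean != a_vit) |
       is.na(a_mod) | is.na(a_mean))
  lab[disagree] <- "unknown"
  lab[is.na(lab)] <- "unknown"
  if (!is.null(cooling_flags)) {
    stopifnot(length(cooling_flags) == length(lab))
    lab[cooling_flags] <- "cooling waters"
  }
  structure(data.frame(date = track$dates, area = lab,
                       lat = track$viterbi$lat, lon = track$viterbi$lon),
            class = c("area_track", "data.frame"))
}

#' Classify the migration strategy of a track
#'
#' The strategy is the most distal area class reached for at least
#' `min_days` known-label days, on the ordering North Sea < English
#' Channel E < English Channel W < Celtic Sea-Bay of Biscay. English
#' Channel days are split east/west of `ec_split_lon` (default 1 deg W). A
#' fish that never leaves the North Sea is "North Sea"; series of 90 days
#' or fewer are "unclassified".
#'
#' @param area_track An [assign_areas()] result.
#' @param min_days Persistence threshold in days (default 5).
#' @param ec_split_lon Longitude splitting the English Channel (default
#'   -1.0, i.e. 1 deg W).
#' @return One of `"North Sea"`, `"English Channel E"`,
#'   `"English Channel W"`, `"Celtic Sea-Bay of Biscay"`,
#'   `"unclassified"`.
#' @export
classify_strategy <- function(area_track, min_days = 5,
                              ec_split_lon = -1.0) {
  if (nrow(area_track) <= 90) return("unclassified")
  lab <- area_track$area
  cls <- rep(NA_character_, length(lab))
  cls[lab == "North Sea"] <- "North Sea"
  ec <- lab == "English Channel"
  cls[ec & area_track$lon > ec_split_lon] <- "English Channel E"
  cls[ec & area_track$lon <= ec_split_lon] <- "English Channel W"
  cls[lab %in% c("Celtic Sea", "Bay of Biscay")] <-
    "Celtic Sea-Bay of Biscay"
  ordering <- c("North Sea", "English Channel E", "English Channel W",
                "Celtic Sea-Bay of Biscay")
  counts <- table(factor(cls, levels = ordering))
  distal <- which(counts >= min_days)
  if (length(distal) == 0) {
    # no class persists: fall back to the commonest known label, else NS
    if (all(is.na(cls))) return("unclassified")
    return(names(which.max(counts)))
  }
  ordering[max(distal)]
}

#' Per-strategy summary table
#'
#' Cumulative Viterbi distance travelled, fitted diffusion coefficient and
#' depth/temperature experience per migration strategy, as
#' median [min-max] over the member fish.
#'
#' @param tracks Named list of `posterior_track`s.
#' @param strategies Character vector of strategies, parallel to `tracks`.
#' @param dailies Optional named list of `daily_obs` data frames (for the
#'   depth/temperature experience).
#' @return Data frame, one row per non-empty strategy: `strategy, n,
#'   distance_km_median, distance_km_min, distance_km_max, D_median,
#'   D_min, D_max`, plus depth/temperature columns when `dailies` given.
#' @export
strategy_summary <- function(tracks, strategies, dailies = NULL) {
  stopifnot(length(tracks) == length(strategies))
  dist_of <- function(tr) {
    v <- tr$viterbi
    if (nrow(v) < 2) return(0)
    sum(haversine_km(v$lat[-nrow(v)], v$lon[-nrow(v)],
                     v$lat[-1], v$lon[-1]))
  }
  dists <- vapply(tracks, dist_of, numeric(1))
  Ds <- vapply(tracks, function(tr) {
    if (!is.null(tr$D_high) && !is.na(tr$D_high)) {
      mean(c(tr$D_low, tr$D_high))
    } else {
      tr$D
    }
  }, numeric(1))
  out <- list()
  for (s in unique(strategies)) {
    i <- which(strategies == s)
    row <- data.frame(
      strategy = s, n = length(i),
      distance_km_median = stats::median(dists[i]),
      distance_km_min = min(dists[i]), distance_km_max = max(dists[i]),
      D_median = stats::median(Ds[i]), D_min = min(Ds[i]),
      D_max = max(Ds[i]))
    if (!is.null(dailies)) {
      dep <- unlist(lapply(dailies[i], function(d) d$max_depth))
      tmp <- unlist(lapply(dailies[i], function(d) d$mean_temp))
      row$depth_median <- stats::median(dep)
      row$depth_min <- min(dep); row$depth_max <- max(dep)
      row$temp_median <- stats::median(tmp)
      row$temp_min <- min(tmp); row$temp_max <- max(tmp)
    }
    out[[s]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residency summary for one tag
#'
#' Table-shaped per-tag summary: time at large, detection positive days
#' and residency index for the tagging-area stations and the full (North
#' Sea) station set, plus the two fidelity booleans.
#'
#' @param det A QC'd [detection_set()].
#' @param tag_id Tag identifier.
#' @param tagging_date Date of tagging.
#' @param area_station_ids Stations of the tagging area.
#' @param ns_station_ids Stations of the North Sea (default: all).
#' @param battery_end,recapture_date Optional dates bounding the time at
#'   large.
#' @return One-row data frame of class `residency_summary`.
#' @export
residency_summary <- function(det, tag_id, tagging_date,
                              area_station_ids,
                              ns_station_ids = det$stations$station_id,
                              battery_end = NA, recapture_date = NA) {
  d <- det$detections[det$detections$tag_id == tag_id, , drop = FALSE]
  last_obs <- if (nrow(d) > 0) max(as.Date(d$timestamp, tz = "UTC"))
              else as.Date(tagging_date) + 1
  # a tag only seen on its tagging day still has one day at large
  last_obs <- max(last_obs, as.Date(tagging_date) + 1)
  tal <- time_at_large(tagging_date, battery_end, recapture_date, last_obs)
  dpd_a <- detection_positive_days(det, tag_id, area_station_ids)
  dpd_ns <- detection_positive_days(det, tag_id, ns_station_ids)
  in_area <- d$station_id %in% area_station_ids
  in_ns <- d$station_id %in% ns_station_ids
  out <- data.frame(
    tag_id = tag_id, time_at_large = as.integer(tal),
    DPD_area = dpd_a, DPD_NS = dpd_ns,
    RI_area = residency_index(dpd_a, tal),
    RI_NS = residency_index(dpd_ns, tal),
    fidelity_area = fidelity(as.Date(d$timestamp[in_area], tz = "UTC"),
                             tagging_date),
    fidelity_NS = fidelity(as.Date(d$timestamp[in_ns], tz = "UTC"),
                           tagging_date))
  class(out) <- c("residency_summary", "data.frame")
  out
}

#' Build a seasonal movement network from detections
#'
#' Nodes are user-defined station groups carrying the number of distinct
#' animals detected; directed edges count consecutive-detection
#' transitions between distinct groups per tag, attributed to the season
#' of the origin detection.
#'
#' @param det A QC'd [detection_set()].
#' @param station_groups Named character vector mapping `station_id` to a
#'   group label.
#' @return Object of class `movement_network`: list with `nodes` (`group,
#'   n_animals`, per-season animal counts) and `edges` (`from, to,
#'   season, count`).
#' @export
build_network <- function(det, station_groups) {
  d <- det$detections
  unknown <- setdiff(unique(d$station_id), names(station_groups))
  if (length(unknown) > 0) {
    stop("build_network: stations not in grouping map: ",
         paste(unknown, collapse = ", "))
  }
  d <- d[order(d$tag_id, d$timestamp), , drop = FALSE]
  d$group <- unname(station_groups[d$station_id])
  d$season <- season_of(as.Date(d$timestamp, tz = "UTC"))
  nodes <- do.call(rbind, lapply(unique(d$group), function(g) {
    dg <- d[d$group == g, ]
    row <- data.frame(group = g, n_animals = length(unique(dg$tag_id)))
    for (s in levels(d$season)) {
      row[[paste0("n_", gsub("-", "_", s))]] <-
        length(unique(dg$tag_id[dg$season == s]))
    }
    row
  }))
  edges <- list()
  for (tag in unique(d$tag_id)) {
    dt <- d[d$tag_id == tag, ]
    if (nrow(dt) < 2) next
    from <- dt$group[-nrow(dt)]; to <- dt$group[-1]
    season <- dt$season[-nrow(dt)]
    move <- from != to
    if (any(move)) {
      edges[[tag]] <- data.frame(from = from[move], to = to[move],
                                 season = season[move])
    }
  }
  if (length(edges) > 0) {
    e <- do.call(rbind, edges)
    edges <- stats::aggregate(count ~ from + to + season,
                              data = cbind(e, count = 1L), FUN = sum)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        season = factor(character(0),
                                        levels = levels(d$season)),
                        count = integer(0))
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "movement_network")
}

#' @export
print.movement_network <- function(x, ...) {
  cat("<movement_network>", nrow(x$nodes), "nodes,",
      nrow(x$edges), "distinct directed edges (total weight",
      sum(x$edges$count), ")\n")
  invisible(x)
}
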