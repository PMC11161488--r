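# Raw tag series -> clean daily observations: depth-drift correction, daily
# summaries, mortality truncation, cooling-water and inshore flags,
# detection quality control.

#' Correct depth-sensor drift with a running minimum
#'
#' Demersal fish that surface regularly should show a per-window minimum
#' depth near 0 m; a drifting pressure sensor strays from it. The corrected
#' depth is the recorded depth minus a centred running minimum over a
#' `window`-day period (edge windows shrink symmetrically), clamped at 0.
#' Temperature is untouched.
#'
#' @param series A [tag_series()].
#' @param window Window length in days (odd; default 7).
#' @return A corrected `tag_series`.
#' @export
correct_depth_drift <- function(series, window = 7) {
  stopifnot(inherits(series, "tag_series"))
  if (window < 1) stop("correct_depth_drift: window must be >= 1 day")
  day <- as.Date(series$data$timestamp, tz = "UTC")
  udays <- sort(unique(day))
  dmin <- tapply(series$data$depth_m, factor(day, levels = udays), min)
  n <- length(udays)
  half <- floor(window / 2)
  runmin <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)   # symmetric shrink at the edges
    runmin[i] <- min(dmin[(i - h):(i + h)])
  }
  corr <- runmin[match(day, udays)]
  series$data$depth_m <- pmax(series$data$depth_m - corr, 0)
  series
}

#' Summarise a tag series to daily observations
#'
#' One row per calendar day (UTC): max/min/median depth, mean temperature,
#' temperature range, and the vertical activity index (sum of absolute
#' successive depth differences within the day). Days with fewer than 2
#' samples get an undefined (NA) activity index and are flagged.
#'
#' @param series A (drift-corrected) [tag_series()].
#' @return Data frame of class `daily_obs` with columns `date, max_depth,
#'   min_depth, med_depth, mean_temp, temp_range, activity_index,
#'   cooling_water, inshore_variability, presumed_dead, sparse`.
#' @export
summarize_daily <- function(series) {
  stopifnot(inherits(series, "tag_series"))
  day <- as.Date(series$data$timestamp, tz = "UTC")
  sp <- split(seq_along(day), day)
  rows <- lapply(names(sp), function(d) {
    i <- sp[[d]]
    z <- series$data$depth_m[i]
    tc <- series$data$temp_c[i]
    data.frame(
      date = as.Date(d),
      max_depth = max(z), min_depth = min(z),
      med_depth = stats::median(z),
      mean_temp = mean(tc), temp_range = diff(range(tc)),
      activity_index = if (length(z) >= 2) sum(abs(diff(z))) else NA_real_,
      sparse = length(z) < 2)
  })
  out <- do.call(rbind, rows)
  out$cooling_water <- FALSE
  out$inshore_variability <- FALSE
  out$presumed_dead <- FALSE
  class(out) <- c("daily_obs", "data.frame")
  out
}

#' Detect tag mortality from daily activity
#'
#' A dead fish (tag resting on the seabed) produces a flat depth record. The
#' rule: the earliest date from which the activity index stays below
#' `activity_thresh` and the within-day depth range below `range_thresh`
#' through the end of the record, for at least `min_run` consecutive days.
#' `alive_until` is the day before that run starts; with no such terminal
#' run, the last date.
#'
#' @param daily A `daily_obs` data frame (>= 7 rows).
#' @param activity_thresh Activity index threshold (m/day, default 1).
#' @param range_thresh Depth-range threshold (m, default 0.5).
#' @param min_run Minimum run length in days (default 7).
#' @return The `alive_until` date.
#' @export
detect_mortality <- function(daily, activity_thresh = 1,
                             range_thresh = 0.5, min_run = 7) {
  stopifnot(nrow(daily) >= min_run)
  flat <- !is.na(daily$activity_index) &
    daily$activity_index < activity_thresh &
    (daily$max_depth - daily$min_depth) < range_thresh
  n <- nrow(daily)
  # earliest start of a flat run reaching the end of the record
  start <- n + 1L
  for (i in rev(seq_len(n))) {
    if (flat[i]) start <- i else break
  }
  daily$date[if (n - start + 1 >= min_run) max(start - 1, 1) else n]
}

#' Flag cooling-water plume days
#'
#' A day is flagged when the tag's mean temperature exceeds the domain-wide
#' maximum water temperature of the reference field for that date by more
#' than `delta_T_flag` while the fish stays shallow -- artificially warmed
#' water cannot be matched by any cell of the field.
#'
#' @param daily A `daily_obs` data frame.
#' @param field A `gridded_field` covering the dates.
#' @param delta_T_flag Exceedance threshold (deg C, default 2).
#' @param max_depth_flag Maximum daily depth for a plume day (m, default 15).
#' @return `daily` with the `cooling_water` flag filled in.
#' @export
flag_plume_days <- function(daily, field, delta_T_flag = 2,
                            max_depth_flag = 15) {
  water <- field$bathymetry > 0
  idx <- match(daily$date, field$dates)
  dmax <- vapply(idx, function(t) {
    if (is.na(t)) return(NA_real_)
    max(field$temp_surface[, , t][water])
  }, numeric(1))
  daily$cooling_water <- !is.na(dmax) &
    daily$mean_temp > dmax + delta_T_flag &
    daily$max_depth < max_depth_flag
  daily
}

#' Truncate a series at the onset of shallow-water temperature variability
#'
#' Sustained large diel temperature swings in very shallow water are not
#' represented in coarse temperature reference fields; the series is only
#' usable for geolocation before that behaviour starts. The rule: at least
#' `min_run` consecutive days with temperature range above `range_thresh`
#' and maximum depth below `depth_thresh`; the truncation date is the first
#' day of the first such run, otherwise the last date.
#'
#' @param daily A `daily_obs` data frame.
#' @param range_thresh Temperature-range threshold (deg C, default 5).
#' @param depth_thresh Depth threshold (m, default 5).
#' @param min_run Run length (days, default 7).
#' @return Truncation date.
#' @export
truncate_inshore_variability <- function(daily, range_thresh = 5,
                                         depth_thresh = 5, min_run = 7) {
  hot <- daily$temp_range > range_thresh & daily$max_depth < depth_thresh
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values & r$lengths >= min_run)
  if (length(k) == 0) daily$date[nrow(daily)] else daily$date[starts[k[1]]]
}

#' Quality-control acoustic detections
#'
#' Two removal rules, applied in order: (a) a detection that is the only
#' detection of its tag on an entire receiver array is unreliable and
#' removed; (b) an isolated detection implying an out-and-back movement of
#' more than `max_km` relative to its flanking detections within the same
#' day is removed.
#'
#' @param det A [detection_set()].
#' @param max_km Implausible out-and-back distance (km, default 100).
#' @return A QC'd `detection_set` with attribute `qc_removed` counting
#'   removals per rule.
#' @export
qc_detections <- function(det, max_km = 100) {
  stopifnot(inherits(det, "detection_set"))
  d <- det$detections
  st <- det$stations
  if (nrow(d) == 0) return(det)
  if (!all(d$station_id %in% st$station_id)) {
    stop("qc_detections: unknown station_id in detections")
  }
  arr <- st$array[match(d$station_id, st$station_id)]
  # (a) array singletons per tag
  key <- paste(d$tag_id, arr, sep = "\r")
  singleton <- key %in% names(which(table(key) == 1))
  n_singleton <- sum(singleton)
  d <- d[!singleton, , drop = FALSE]
  # (b) same-day out-and-back over max_km
  n_implausible <- 0L
  keep <- rep(TRUE, nrow(d))
  d <- d[order(d$tag_id, d$timestamp), , drop = FALSE]
  slat <- st$lat[match(d$station_id, st$station_id)]
  slon <- st$lon[match(d$station_id, st$station_id)]
  for (tag in unique(d$tag_id)) {
    i <- which(d$tag_id == tag)
    if (length(i) < 3) next
    for (k in 2:(length(i) - 1)) {
      a <- i[k - 1]; b <- i[k]; cc <- i[k + 1]
      if (d$station_id[b] == d$station_id[a] ||
          d$station_id[b] == d$station_id[cc]) next
      d_ab <- haversine_km(slat[a], slon[a], slat[b], slon[b])
      d_bc <- haversine_km(slat[b], slon[b], slat[cc], slon[cc])
      same_day <- as.numeric(difftime(d$timestamp[cc], d$timestamp[a],
                                      units = "days")) <= 1
      if (d_ab > max_km && d_bc > max_km && same_day) {
        keep[b] <- FALSE
        n_implausible <- n_implausible + 1L
      }
    }
  }
  d <- d[keep, , drop = FALSE]
  out <- detection_set(st, d)
  attr(out, "qc_removed") <- c(array_singleton = n_singleton,
                               implausible_movement = n_implausible)
  out
}

#' Preprocess a raw tag series into a clean series
#'
#' Applies, in order: drift correction, daily summarisation, mortality
#' truncation, cooling-water flagging (when a field is supplied) and
#' inshore-variability truncation. The returned object carries the daily
#' observations restricted to release..alive_until and the geolocation
#' truncation date. Thresholds are exposed so per-tag manual overrides
#' remain possible; the flags are heuristics and are reported as such.
#'
#' @param series A raw [tag_series()].
#' @param field Optional `gridded_field` for plume flagging.
#' @param drift_window Running-minimum window (days).
#' @param mortality,inshore,plume Named lists overriding the rule thresholds
#'   (see [detect_mortality()], [truncate_inshore_variability()],
#'   [flag_plume_days()]).
#' @return Object of class `clean_series`: list with the corrected
#'   `series`, `daily`, `alive_until`, `truncation_date`.
#' @export
preprocess_tag <- function(series, field = NULL, drift_window = 7,
                           mortality = list(), inshore = list(),
                           plume = list()) {
  corrected <- correct_depth_drift(series, window = drift_window)
  daily <- summarize_daily(corrected)
  alive_until <- do.call(detect_mortality, c(list(daily), mortality))
  daily$presumed_dead <- daily$date > alive_until
  if (!is.null(field)) {
    daily <- do.call(flag_plume_days, c(list(daily, field), plume))
  }
  trunc_date <- do.call(truncate_inshore_variability, c(list(daily), inshore))
  daily$inshore_variability <- daily$date >= trunc_date &
    trunc_date < daily$date[nrow(daily)]
  structure(list(series = corrected, daily = daily,
                 alive_until = alive_until,
                 truncation_date = min(trunc_date, alive_until)),
            class = "clean_series")
}

#' @export
print.clean_series <- function(x, ...) {
  cat("<clean_series>", x$series$tag_id, "|", nrow(x$daily), "days\n")
  cat("  alive until:", format(x$alive_until),
      "| geolocation truncation:", format(x$truncation_date), "\n")
  cat("  cooling-water days:", sum(x$daily$cooling_water),
      "| inshore-variability days:", sum(x$daily$inshore_variability), "\n")
  invisible(x)
}

#' Daily observations usable for geolocation
#'
#' Restricts a clean series to the days between release and the earlier of
#' the mortality and inshore truncation dates.
#'
#' @param clean A `clean_series`.
#' @return A `daily_obs` data frame.
#' @export
usable_daily <- function(clean) {
  d <- clean$daily
  d[d$date <= clean$truncation_date, , drop = FALSE]
}
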