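#' @keywords internal
"_PACKAGE"

#' Great-circle distance between points (haversine)
#'
#' Distance on a sphere of radius 6371 km between points given in WGS84
#' decimal degrees. Vectorised over both arguments; arguments recycle.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(!is.finite(c(lat1, lon1, lat2, lon2)))) {
    stop("haversine_km: coordinates must be finite")
  }
  if (any(abs(c(lat1, lat2)) > 90)) {
    stop("haversine_km: |latitude| must be <= 90")
  }
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * r * asin(sqrt(a))
}

# Pairwise distance matrix (km) between two coordinate sets, via outer sums of
# the haversine terms. Used for kernel construction on grids.
haversine_matrix_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  sdlat <- sin(outer(lat2, lat1, "-") * to_rad / 2)^2
  sdlon <- sin(outer(lon2, lon1, "-") * to_rad / 2)^2
  cc <- outer(cos(lat2 * to_rad), cos(lat1 * to_rad))
  a <- pmin(sdlat + cc * sdlon, 1)
  t(2 * r * asin(sqrt(a)))
}

#' Meteorological season of a date
#'
#' Month-based season labels: December groups with the January and February
#' that follow it, i.e. Dec 2015 belongs to the same winter as Jan/Feb 2016.
#'
#' @param date A `Date` vector (or something coercible with `as.Date`).
#' @return Factor with levels `"Dec-Feb"`, `"Mar-May"`, `"Jun-Aug"`,
#'   `"Sep-Nov"`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  lab <- c("Dec-Feb", "Dec-Feb", "Mar-May", "Mar-May", "Mar-May",
           "Jun-Aug", "Jun-Aug", "Jun-Aug", "Sep-Nov", "Sep-Nov",
           "Sep-Nov", "Dec-Feb")[m]
  factor(lab, levels = c("Dec-Feb", "Mar-May", "Jun-Aug", "Sep-Nov"))
}

#' Construct a tag sensor series
#'
#' An archival (data storage) tag record: timestamped depth and temperature
#' samples plus release (and optionally recovery) anchors.
#'
#' @param tag_id Character scalar.
#' @param data Data frame with columns `timestamp` (POSIXct, UTC),
#'   `depth_m` (metres, positive down) and `temp_c` (degrees Celsius).
#' @param sampling_interval Nominal sampling interval in seconds.
#' @param release List with `date` (Date), `lat`, `lon`.
#' @param recovery Optional list with `date`, `lat`, `lon`.
#' @return Object of class `tag_series`.
#' @export
tag_series <- function(tag_id, data, sampling_interval, release,
                       recovery = NULL) {
  stopifnot(is.character(tag_id), length(tag_id) == 1L)
  req <- c("timestamp", "depth_m", "temp_c")
  if (!all(req %in% names(data))) {
    stop("tag_series: data must have columns ", paste(req, collapse = ", "))
  }
  if (!inherits(data$timestamp, "POSIXct")) {
    stop("tag_series: timestamp must be POSIXct")
  }
  if (is.unsorted(data$timestamp, strictly = TRUE)) {
    stop("tag_series: timestamps must be strictly increasing")
  }
  if (any(!is.finite(data$depth_m))) stop("tag_series: depth must be finite")
  if (any(data$depth_m < -1)) {
    stop("tag_series: depths below -1 m are not sensor noise; refusing")
  }
  # small negative depths are surface noise
  data$depth_m <- pmax(data$depth_m, 0)
  release$date <- as.Date(release$date)
  if (release$date > as.Date(data$timestamp[1], tz = "UTC") + 1) {
    stop("tag_series: release date after first sample + 1 day")
  }
  structure(
    list(tag_id = tag_id, data = data,
         sampling_interval = sampling_interval,
         release = release, recovery = recovery),
    class = "tag_series"
  )
}

#' @export
print.tag_series <- function(x, ...) {
  cat("<tag_series>", x$tag_id, "\n")
  cat("  samples:", nrow(x$data), "every", x$sampling_interval, "s\n")
  cat("  span:", format(min(x$data$timestamp)), "to",
      format(max(x$data$timestamp)), "UTC\n")
  cat(sprintf("  release: %s at (%.3f, %.3f)\n",
              format(x$release$date), x$release$lat, x$release$lon))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: %s at (%.3f, %.3f)\n",
                format(as.Date(x$recovery$date)), x$recovery$lat,
                x$recovery$lon))
  }
  invisible(x)
}

#' Construct a gridded environmental field
#'
#' A regular lat/lon grid carrying bathymetry (metres, positive down; values
#' <= 0 are land) and daily surface/bottom temperature layers.
#'
#' @param lat,lon Cell-centre coordinate vectors, regularly spaced degrees.
#' @param dates Date vector (one temperature layer per date).
#' @param bathymetry Matrix `length(lat) x length(lon)`.
#' @param temp_surface,temp_bottom Arrays
#'   `length(lat) x length(lon) x length(dates)`.
#' @return Object of class `gridded_field`.
#' @export
gridded_field <- function(lat, lon, dates, bathymetry, temp_surface,
                          temp_bottom) {
  check_uniform <- function(v, nm) {
    if (length(v) > 1) {
      d <- diff(v)
      if (max(abs(d - d[1])) > 1e-8 * abs(d[1])) {
        stop("gridded_field: non-uniform ", nm, " spacing")
      }
    }
  }
  check_uniform(lat, "lat")
  check_uniform(lon, "lon")
  dates <- as.Date(dates)
  stopifnot(identical(dim(bathymetry), c(length(lat), length(lon))))
  dd <- c(length(lat), length(lon), length(dates))
  stopifnot(identical(dim(temp_surface), dd), identical(dim(temp_bottom), dd))
  water <- bathymetry > 0
  for (a in list(temp_surface, temp_bottom)) {
    wt <- a[rep(water, length(dates))]
    if (any(!is.finite(wt))) {
      stop("gridded_field: temperature undefined on water cells")
    }
  }
  structure(
    list(lat = lat, lon = lon, dates = dates, bathymetry = bathymetry,
         temp_surface = temp_surface, temp_bottom = temp_bottom),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  cat("<gridded_field>", length(x$lat), "x", length(x$lon), "cells,",
      length(x$dates), "days\n")
  cat(sprintf("  lat %.3f..%.3f  lon %.3f..%.3f\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  water cells: %d (%.0f%%), max depth %.1f m\n",
              sum(x$bathymetry > 0),
              100 * mean(x$bathymetry > 0), max(x$bathymetry)))
  cat("  dates:", format(min(x$dates)), "to", format(max(x$dates)), "\n")
  invisible(x)
}

#' Land mask of a gridded field
#' @param field A `gridded_field`.
#' @return Logical matrix, `TRUE` on land (bathymetry <= 0).
#' @export
land_mask <- function(field) field$bathymetry <= 0

#' Construct an acoustic detection set
#'
#' @param stations Data frame with `station_id`, `lat`, `lon`, `array`.
#' @param detections Data frame with `tag_id`, `timestamp` (POSIXct UTC),
#'   `station_id`. May have zero rows.
#' @return Object of class `detection_set`.
#' @export
detection_set <- function(stations, detections) {
  stopifnot(all(c("station_id", "lat", "lon", "array") %in% names(stations)))
  stopifnot(all(c("tag_id", "timestamp", "station_id") %in% names(detections)))
  if (nrow(detections) > 0 &&
      !all(detections$station_id %in% stations$station_id)) {
    stop("detection_set: detections reference unknown station_id")
  }
  structure(list(stations = stations, detections = detections),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat("<detection_set>", nrow(x$detections), "detections of",
      length(unique(x$detections$tag_id)), "tags on",
      nrow(x$stations), "stations\n")
  invisible(x)
}

#' Construct mark-recapture records
#'
#' @param df Data frame with `tag_id`, `release_date`, `release_lat`,
#'   `release_lon`, `recapture_date`, `recapture_lat`, `recapture_lon`.
#' @return The data frame with `days_at_large` and `distance_km` appended,
#'   class `recapture_records`.
#' @export
recapture_records <- function(df) {
  req <- c("tag_id", "release_date", "release_lat", "release_lon",
           "recapture_date", "recapture_lat", "recapture_lon")
  stopifnot(all(req %in% names(df)))
  df$release_date <- as.Date(df$release_date)
  df$recapture_date <- as.Date(df$recapture_date)
  if (any(df$recapture_date < df$release_date)) {
    stop("recapture_records: recapture before release")
  }
  df$days_at_large <- as.integer(df$recapture_date - df$release_date)
  df$distance_km <- haversine_km(df$release_lat, df$release_lon,
                                 df$recapture_lat, df$recapture_lon)
  class(df) <- c("recapture_records", "data.frame")
  df
}

#' Construct a named area set
#'
#' Named polygons partitioning the marine domain (ICES-division-like areas),
#' optionally with cooling-water point sources.
#'
#' @param areas Named list; each element a list with numeric vectors `lon`
#'   and `lat` describing a simple polygon ring (not closed).
#' @param cooling_sources Optional data frame with `lat`, `lon`, `radius_km`.
#' @param check_overlap Verify polygons are non-overlapping (vertex-in-other
#'   polygon test). Default `TRUE`.
#' @return Object of class `area_set`.
#' @export
area_set <- function(areas, cooling_sources = NULL, check_overlap = TRUE) {
  stopifnot(is.list(areas), !is.null(names(areas)), all(nzchar(names(areas))))
  for (a in areas) stopifnot(length(a$lon) >= 3, length(a$lon) == length(a$lat))
  if (check_overlap && length(areas) > 1) {
    nm <- names(areas)
    for (i in seq_along(areas)) {
      for (j in seq_along(areas)) {
        if (i == j) next
        # interior points of i must not fall strictly inside j
        mid_lon <- mean(areas[[i]]$lon)
        mid_lat <- mean(areas[[i]]$lat)
        inside_own <- pracma::inpolygon(mid_lon, mid_lat,
                                        areas[[i]]$lon, areas[[i]]$lat)
        inside_other <- pracma::inpolygon(mid_lon, mid_lat,
                                          areas[[j]]$lon, areas[[j]]$lat,
                                          boundary = FALSE)
        if (inside_own && inside_other) {
          stop("area_set: polygons overlap: ", nm[i], " and ", nm[j])
        }
      }
    }
  }
  structure(list(areas = areas, cooling_sources = cooling_sources),
            class = "area_set")
}

#' @export
print.area_set <- function(x, ...) {
  cat("<area_set>", length(x$areas), "areas:",
      paste(names(x$areas), collapse = ", "), "\n")
  if (!is.null(x$cooling_sources)) {
    cat("  cooling-water sources:", nrow(x$cooling_sources), "\n")
  }
  invisible(x)
}

#' Assign points to named areas
#'
#' @param lat,lon Point coordinates (vectors).
#' @param areas An `area_set`.
#' @return Character vector of area names, `NA` where a point falls in no
#'   polygon.
#' @export
locate_area <- function(lat, lon, areas) {
  stopifnot(inherits(areas, "area_set"))
  out <- rep(NA_character_, length(lat))
  for (nm in names(areas$areas)) {
    p <- areas$areas[[nm]]
    hit <- pracma::inpolygon(lon, lat, p$lon, p$lat)
    out[is.na(out) & hit] <- nm
  }
  out
}
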