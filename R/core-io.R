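# Readers and writers for the package's on-disk formats.
#
# Schemas (header row mandatory, comma separated, ISO-8601 timestamps, UTC):
#   tag series:  tag_id,timestamp,depth_m,temp_c
#   detections:  tag_id,timestamp,station_id
#   stations:    station_id,lat,lon,array
#   recaptures:  tag_id,release_date,release_lat,release_lon,
#                recapture_date,recapture_lat,recapture_lon
# GriddedField: NetCDF, dims (lon, lat, time), vars bathymetry,
#               temp_surface, temp_bottom.
# AreaSet:      GeoJSON FeatureCollection, property "name".

parse_utc <- function(x, what) {
  out <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                              "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), length(x)))
  if (any(is.na(out) & !is.na(x))) {
    stop("unparseable timestamps in ", what, ": e.g. ",
         x[which(is.na(out) & !is.na(x))[1]])
  }
  out
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, ": missing required columns: ", paste(miss, collapse = ", "))
  }
}

#' Read a tag sensor series from CSV
#'
#' @param path CSV with columns `tag_id,timestamp,depth_m,temp_c`.
#' @param release List with `date`, `lat`, `lon` (release anchor).
#' @param recovery Optional recovery anchor (list with `date`, `lat`, `lon`).
#' @param sampling_interval Sampling interval in seconds; inferred from the
#'   median timestamp difference when `NULL`.
#' @return A [tag_series()].
#' @export
read_tag_series <- function(path, release, recovery = NULL,
                            sampling_interval = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tag_id", "timestamp", "depth_m", "temp_c"),
                  "tag series CSV")
  df$timestamp <- parse_utc(df$timestamp, "tag series CSV")
  bad <- !is.finite(df$depth_m) | !is.finite(df$temp_c) | is.na(df$timestamp)
  if (any(bad)) {
    message("read_tag_series: rejected ", sum(bad), " malformed rows")
    df <- df[!bad, , drop = FALSE]
  }
  if (is.null(sampling_interval)) {
    sampling_interval <-
      as.numeric(stats::median(diff(as.numeric(df$timestamp))))
  }
  tag_series(df$tag_id[1],
             df[, c("timestamp", "depth_m", "temp_c")],
             sampling_interval, release, recovery)
}

#' Write a tag sensor series to CSV
#' @param x A `tag_series`.
#' @param path Output path.
#' @export
write_tag_series <- function(x, path) {
  df <- data.frame(tag_id = x$tag_id,
                   timestamp = format(x$data$timestamp,
                                      "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   depth_m = x$data$depth_m, temp_c = x$data$temp_c)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read acoustic detections and stations from CSV
#'
#' @param detections_path CSV `tag_id,timestamp,station_id`; may be empty
#'   (header only).
#' @param stations_path CSV `station_id,lat,lon,array`.
#' @return A [detection_set()].
#' @export
read_detections <- function(detections_path, stations_path) {
  st <- utils::read.csv(stations_path, stringsAsFactors = FALSE)
  require_columns(st, c("station_id", "lat", "lon", "array"), "stations CSV")
  de <- utils::read.csv(detections_path, stringsAsFactors = FALSE,
                        colClasses = c(tag_id = "character",
                                       station_id = "character"))
  require_columns(de, c("tag_id", "timestamp", "station_id"),
                  "detections CSV")
  de$timestamp <- if (nrow(de) > 0) {
    parse_utc(de$timestamp, "detections CSV")
  } else {
    as.POSIXct(character(0), tz = "UTC")
  }
  detection_set(st, de)
}

#' Write a detection set to CSV
#' @param x A `detection_set`.
#' @param detections_path,stations_path Output paths.
#' @export
write_detections <- function(x, detections_path, stations_path) {
  de <- x$detections
  de$timestamp <- format(de$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(de, detections_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$stations, stations_path, row.names = FALSE, quote = FALSE)
  invisible(detections_path)
}

#' Read mark-recapture records from CSV
#' @param path CSV with the recapture schema (see package README).
#' @return A [recapture_records()] data frame.
#' @export
read_recaptures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  recapture_records(df)
}

#' Write mark-recapture records to CSV
#' @param x A `recapture_records` data frame.
#' @param path Output path.
#' @export
write_recaptures <- function(x, path) {
  keep <- c("tag_id", "release_date", "release_lat", "release_lon",
            "recapture_date", "recapture_lat", "recapture_lon")
  utils::write.csv(as.data.frame(x)[, keep], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded field from NetCDF
#'
#' Expects dimensions `lon`, `lat`, `time` (days since an epoch date) and
#' variables `bathymetry(lon,lat)`, `temp_surface(lon,lat,time)`,
#' `temp_bottom(lon,lat,time)`.
#'
#' @param path NetCDF file.
#' @return A [gridded_field()].
#' @export
read_field_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  tvals <- as.numeric(nc$dim$time$vals)
  tunits <- nc$dim$time$units
  epoch <- as.Date(sub("^days since ", "", tunits))
  dates <- epoch + tvals
  bathy <- t(ncdf4::ncvar_get(nc, "bathymetry"))
  get3 <- function(v) {
    a <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
    aperm(a, c(2, 1, 3))
  }
  gridded_field(lat, lon, dates, bathy,
                get3("temp_surface"), get3("temp_bottom"))
}

#' Write a gridded field to NetCDF
#' @param field A `gridded_field`.
#' @param path Output path.
#' @export
write_field_nc <- function(field, path) {
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dtime <- ncdf4::ncdim_def(
    "time", paste("days since", format(field$dates[1])),
    as.numeric(field$dates - field$dates[1]), unlim = TRUE)
  vb <- ncdf4::ncvar_def("bathymetry", "m", list(dlon, dlat), prec = "double")
  vs <- ncdf4::ncvar_def("temp_surface", "degC", list(dlon, dlat, dtime),
                         prec = "double")
  vd <- ncdf4::ncvar_def("temp_bottom", "degC", list(dlon, dlat, dtime),
                         prec = "double")
  nc <- ncdf4::nc_create(path, list(vb, vs, vd))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vb, t(field$bathymetry))
  ncdf4::ncvar_put(nc, vs, aperm(field$temp_surface, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, vd, aperm(field$temp_bottom, c(2, 1, 3)))
  invisible(path)
}

#' Read a named area set from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon features with a `name`
#'   property. An optional FeatureCollection-level property
#'   `cooling_sources` (list of `lat`, `lon`, `radius_km`) is honoured.
#' @param check_overlap Passed to [area_set()].
#' @return An [area_set()].
#' @export
read_area_set <- function(path, check_overlap = TRUE) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("read_area_set: not a GeoJSON FeatureCollection")
  }
  areas <- list()
  for (f in gj$features) {
    nm <- f$properties$name
    if (is.null(nm)) stop("read_area_set: feature without 'name' property")
    ring <- f$geometry$coordinates[[1]]
    lon <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    lat <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    n <- length(lon)
    if (n > 1 && lon[1] == lon[n] && lat[1] == lat[n]) {
      lon <- lon[-n]; lat <- lat[-n]
    }
    areas[[nm]] <- list(lon = lon, lat = lat)
  }
  cs <- NULL
  if (!is.null(gj$properties$cooling_sources)) {
    cs <- do.call(rbind, lapply(gj$properties$cooling_sources, function(s) {
      data.frame(lat = s$lat, lon = s$lon, radius_km = s$radius_km)
    }))
  }
  area_set(areas, cooling_sources = cs, check_overlap = check_overlap)
}

#' Write a named area set to GeoJSON
#' @param x An `area_set`.
#' @param path Output path.
#' @export
write_area_set <- function(x, path) {
  feats <- lapply(names(x$areas), function(nm) {
    p <- x$areas[[nm]]
    ring <- lapply(c(seq_along(p$lon), 1L),
                   function(i) c(p$lon[i], p$lat[i]))
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  if (!is.null(x$cooling_sources)) {
    obj$properties <- list(
      cooling_sources = lapply(seq_len(nrow(x$cooling_sources)), function(i) {
        as.list(x$cooling_sources[i, c("lat", "lon", "radius_km")])
      }))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
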