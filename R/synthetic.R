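# Seeded synthetic biologging data: shelf-sea fields, two-state diffusive
# trajectories, tag sensor series, acoustic detections, recaptures.
# These emulate the statistical structure the geolocation assumes (two-layer
# temperature column, bathymetric gradient towards a coast, distance-dependent
# detection) -- not real hydrodynamics.

#' Simulation configuration
#'
#' Defaults describe a 40 x 40 cell shelf-sea domain at roughly the
#' resolution of operational north-west European shelf temperature products
#' (0.1 deg lat x 0.15 deg lon), a 120-day summer-autumn deployment, and a
#' two-state diffusive fish: low-activity diffusion 5 km^2/day and
#' high-activity 30 km^2/day (the order of magnitude of diffusion
#' coefficients reported for resident vs migrating seabass), sticky
#' behaviour states, 10-minute sensor sampling, and an acoustic tag whose
#' daily detection probability is 50% at 566 m from a receiver.
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so an identical config reproduces the dataset exactly.
#' @param lat0,lon0 South-west cell centre (degrees).
#' @param dlat,dlon Grid spacing (degrees).
#' @param nlat,nlon Grid size (cells).
#' @param start_date First day of the simulation.
#' @param n_days Number of days.
#' @param D_low,D_high Diffusion coefficients (km^2/day) of the two
#'   behaviour states.
#' @param trans 2x2 behaviour transition matrix (rows sum to 1; state 1 =
#'   low activity).
#' @param sigma_T Temperature sensor noise sd (deg C).
#' @param sigma_z Depth sensor noise sd (m).
#' @param sampling_interval Sensor sampling interval (seconds).
#' @param drift_rate Depth-sensor drift (m/day), 0 for none.
#' @param plume_sources Optional data frame `lat,lon,delta_T,radius_km,
#'   start,end` of cooling-water plumes.
#' @param r50_m Distance (m) at which daily detection probability is 0.5.
#' @param n_stations Number of acoustic receiver stations.
#' @param p_recapture Daily recapture probability.
#' @param death_day Optional day index after which the fish is dead (tag
#'   rests on the seabed); `NA` for none.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lat0 = 50.0, lon0 = -2.0,
                       dlat = 0.1, dlon = 0.15,
                       nlat = 40L, nlon = 40L,
                       start_date = as.Date("2015-06-01"),
                       n_days = 120L,
                       D_low = 5, D_high = 30,
                       trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                      byrow = TRUE),
                       sigma_T = 0.5, sigma_z = 0.3,
                       sampling_interval = 600,
                       drift_rate = 0,
                       plume_sources = NULL,
                       r50_m = 566,
                       n_stations = 15L,
                       p_recapture = 0.001,
                       death_day = NA_integer_) {
  stopifnot(D_low >= 0, D_high >= D_low, r50_m > 0,
            nlat >= 5, nlon >= 5, n_days >= 1)
  if (any(abs(rowSums(trans) - 1) > 1e-9) || any(trans < 0)) {
    stop("sim_config: behaviour transition rows must sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$nlat, "x", x$nlon, "grid |",
      x$n_days, "days | D =", x$D_low, "/", x$D_high, "km^2/day\n")
  invisible(x)
}

# Independent substream per generator, kept below 2^31.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483629)
}

#' Generate a synthetic shelf-sea gridded field
#'
#' Bathymetry: a smooth coastline along the eastern edge with depth
#' saturating towards 120 m offshore. Temperatures: a latitudinal gradient
#' plus a seasonal sinusoid (late-summer peak) plus a fixed smooth spatial
#' anomaly; the bottom layer is colder than the surface in summer
#' (stratification scaled by depth) and equal in winter.
#'
#' @param config A [sim_config()].
#' @return A [gridded_field()].
#' @export
gen_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11))
  lat <- config$lat0 + config$dlat * (seq_len(config$nlat) - 1)
  lon <- config$lon0 + config$dlon * (seq_len(config$nlon) - 1)
  nlat <- config$nlat; nlon <- config$nlon
  # coastline: land occupies the 2..5 easternmost columns, wiggling with lat
  ph <- stats::runif(2, 0, 2 * pi)
  land_w <- 2 + round(1.5 * (1 + sin(2 * pi * seq_len(nlat) / nlat + ph[1])))
  coast_col <- nlon - land_w            # last water column per row
  dcells <- outer(rep(1, nlat), seq_len(nlon))
  dist_to_coast <- coast_col - dcells    # >= 0 on water (in cells)
  bathy <- 120 * (1 - exp(-pmax(dist_to_coast + 1, 0) / 8))
  bathy[dist_to_coast < 0] <- -5        # land
  dates <- config$start_date + seq_len(config$n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  # smooth spatial anomaly at mesoscale wavelengths (~200 km) that evolves
  # synoptically (two patterns cross-fading over ~60 days): shelf-sea
  # temperature fields carry this kind of structure, and its slow temporal
  # evolution is what lets a geolocation model separate locations that
  # momentarily share the same temperature
  A1 <- 1.2 * outer(sin(2 * pi * seq_len(nlat) / 18 + ph[2]),
                    cos(2 * pi * seq_len(nlon) / 18 + ph[1])) +
    0.8 * outer(cos(2 * pi * seq_len(nlat) / 31 + ph[1]),
                sin(2 * pi * seq_len(nlon) / 29 + ph[2]))
  A2 <- 1.2 * outer(cos(2 * pi * seq_len(nlat) / 23 + ph[1]),
                    sin(2 * pi * seq_len(nlon) / 21 + ph[2])) +
    0.8 * outer(sin(2 * pi * seq_len(nlat) / 35 + ph[2]),
                cos(2 * pi * seq_len(nlon) / 16 + ph[1]))
  base <- 16 - 0.8 * outer(lat - min(lat), rep(1, nlon))
  seas <- 4.5 * cos(2 * pi * (doy - 228) / 365.25)
  strat_season <- pmax(0, cos(2 * pi * (doy - 213) / 365.25))
  depth_factor <- pmin(1, pmax(bathy, 0) / 50)
  ts <- array(NA_real_, c(nlat, nlon, length(dates)))
  tb <- ts
  for (t in seq_along(dates)) {
    wmix <- 2 * pi * t / 60
    anom <- A1 * cos(wmix) + A2 * sin(wmix)
    s <- base + anom + seas[t]
    ts[, , t] <- s
    tb[, , t] <- s - 3 * strat_season[t] * depth_factor
  }
  gridded_field(lat, lon, dates, bathy, ts, tb)
}

# nearest-cell lookup; returns row/col indices (NA outside the grid)
cell_of <- function(field, lat, lon) {
  i <- round((lat - field$lat[1]) / (field$lat[2] - field$lat[1])) + 1
  j <- round((lon - field$lon[1]) / (field$lon[2] - field$lon[1])) + 1
  i[i < 1 | i > length(field$lat)] <- NA
  j[j < 1 | j > length(field$lon)] <- NA
  cbind(i, j)
}

is_water_at <- function(field, lat, lon) {
  ij <- cell_of(field, lat, lon)
  ok <- !is.na(ij[, 1]) & !is.na(ij[, 2])
  out <- rep(FALSE, length(lat))
  out[ok] <- field$bathymetry[ij[ok, , drop = FALSE]] > 0
  out
}

#' Generate a true fish trajectory
#'
#' A daily two-dimensional Gaussian random walk with per-axis variance
#' `2 * D(state) * 1 day`, reflected off land, behaviour states following
#' the configured Markov chain. If `death_day` is set the position freezes
#' from that day on.
#'
#' @param config A [sim_config()].
#' @param field The [gen_field()] output.
#' @param start Optional start position `c(lat, lon)`; defaults to the
#'   deepest-water cell centre nearest the domain centre.
#' @param tag_id Tag identifier for the truth record.
#' @param seed Stream seed; derived from the config seed by default (pass a
#'   different value per tag to grow a cohort).
#' @return Object of class `truth_record`: data frame `date, lat, lon,
#'   state, alive` with the generating `D_low`/`D_high` attached.
#' @export
gen_trajectory <- function(config, field, start = NULL, tag_id = "sim1",
                           seed = derive_seed(config$seed, 23)) {
  set.seed(seed)
  if (is.null(start)) {
    wc <- which(field$bathymetry > 40, arr.ind = TRUE)
    if (nrow(wc) == 0) wc <- which(field$bathymetry > 0, arr.ind = TRUE)
    ctr <- c(mean(field$lat), mean(field$lon))
    d <- haversine_km(field$lat[wc[, 1]], field$lon[wc[, 2]], ctr[1], ctr[2])
    k <- which.min(d)
    start <- c(field$lat[wc[k, 1]], field$lon[wc[k, 2]])
  }
  if (!is_water_at(field, start[1], start[2])) {
    stop("gen_trajectory: start position on land")
  }
  n <- config$n_days
  Dv <- c(config$D_low, config$D_high)
  state <- integer(n)
  state[1] <- sample(1:2, 1)
  for (t in 2:max(n, 2)) {
    if (t > n) break
    state[t] <- sample(1:2, 1, prob = config$trans[state[t - 1], ])
  }
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- start[1]; lon[1] <- start[2]
  alive <- rep(TRUE, n)
  if (!is.na(config$death_day)) {
    alive[seq_len(n) >= config$death_day] <- FALSE
  }
  km_per_deg <- 111.19
  if (n >= 2) {
    for (t in 2:n) {
      if (!alive[t]) {
        lat[t] <- lat[t - 1]; lon[t] <- lon[t - 1]
        state[t] <- 1L
        next
      }
      sd_km <- sqrt(2 * Dv[state[t - 1]])
      step <- stats::rnorm(2, 0, sd_km)
      dlat <- step[1] / km_per_deg
      dlon <- step[2] / (km_per_deg * cos(lat[t - 1] * pi / 180))
      cand_lat <- lat[t - 1] + dlat
      cand_lon <- lon[t - 1] + dlon
      if (!is_water_at(field, cand_lat, cand_lon)) {
        # reflect the step; if still on land, stay put
        cand_lat <- lat[t - 1] - dlat
        cand_lon <- lon[t - 1] - dlon
        if (!is_water_at(field, cand_lat, cand_lon)) {
          cand_lat <- lat[t - 1]; cand_lon <- lon[t - 1]
        }
      }
      lat[t] <- cand_lat; lon[t] <- cand_lon
    }
  }
  structure(
    data.frame(date = field$dates[seq_len(n)], lat = lat, lon = lon,
               state = state, alive = alive),
    tag_id = tag_id, D_low = config$D_low, D_high = config$D_high,
    class = c("truth_record", "data.frame")
  )
}

#' Generate an archival tag series from a true trajectory
#'
#' Per day, the depth profile is a diel oscillation between the surface and
#' a state-dependent fraction of the local bathymetry (high activity: larger
#' and more frequent excursions), with Gaussian depth noise. Temperature is
#' the two-layer field value linearly interpolated to the sampled depth plus
#' Gaussian sensor noise; cooling-water plume episodes add a fluctuating
#' `delta_T` when the fish is inside an active plume radius. Optional linear
#' depth-sensor drift is applied last. After death the tag rests on the
#' seabed and records an essentially constant depth.
#'
#' @param truth A `truth_record`.
#' @param field The matching `gridded_field`.
#' @param config The [sim_config()].
#' @param seed Stream seed (default derived from config).
#' @return A [tag_series()].
#' @export
gen_tag_series <- function(truth, field, config,
                           seed = derive_seed(config$seed, 37)) {
  set.seed(seed)
  n_days <- nrow(truth)
  ns <- as.integer(round(86400 / config$sampling_interval))
  amp_frac <- c(0.3, 0.9)    # by state
  cycles <- c(1, 3)
  ij <- cell_of(field, truth$lat, truth$lon)
  bathy_d <- field$bathymetry[ij]
  tidx <- match(truth$date, field$dates)
  out <- vector("list", n_days)
  for (t in seq_len(n_days)) {
    b <- bathy_d[t]
    k <- seq_len(ns)
    if (truth$alive[t]) {
      st <- truth$state[t]
      z <- amp_frac[st] * b *
        (0.5 - 0.5 * cos(2 * pi * cycles[st] * k / ns)) +
        stats::rnorm(ns, 0, config$sigma_z)
      z <- pmin(pmax(z, 0), b)
    } else {
      z <- pmin(b + stats::rnorm(ns, 0, 0.002), b)
      z <- pmax(z, 0)
    }
    tsfc <- field$temp_surface[ij[t, 1], ij[t, 2], tidx[t]]
    tbot <- field$temp_bottom[ij[t, 1], ij[t, 2], tidx[t]]
    temp <- tsfc + (z / b) * (tbot - tsfc) +
      stats::rnorm(ns, 0, config$sigma_T)
    if (!is.null(config$plume_sources)) {
      ps <- config$plume_sources
      for (s in seq_len(nrow(ps))) {
        active <- truth$date[t] >= as.Date(ps$start[s]) &
          truth$date[t] <= as.Date(ps$end[s])
        if (active) {
          d <- haversine_km(truth$lat[t], truth$lon[t], ps$lat[s], ps$lon[s])
          if (d <= ps$radius_km[s]) {
            temp <- temp + ps$delta_T[s] * (0.65 + 0.35 * sin(2 * pi * k / ns))
            # plume residence is shallow: cap the dive depth that day
            z <- pmin(z, 10)
          }
        }
      }
    }
    z_rec <- z + config$drift_rate * (t - 1 + k / ns)
    out[[t]] <- data.frame(
      timestamp = as.POSIXct(truth$date[t], tz = "UTC") +
        (k - 1) * config$sampling_interval,
      depth_m = z_rec, temp_c = temp)
  }
  df <- do.call(rbind, out)
  tag_series(attr(truth, "tag_id"), df, config$sampling_interval,
             release = list(date = truth$date[1],
                            lat = truth$lat[1], lon = truth$lon[1]))
}

#' Generate acoustic receiver stations
#'
#' Places stations uniformly over water cells, biased towards shallower
#' (nearshore) water where receiver arrays sit in practice.
#'
#' @param config A [sim_config()].
#' @param field The `gridded_field`.
#' @param seed Stream seed.
#' @return Data frame `station_id, lat, lon, array` (stations are grouped
#'   into arrays of up to 5 by proximity of their index).
#' @export
gen_stations <- function(config, field,
                         seed = derive_seed(config$seed, 53)) {
  set.seed(seed)
  wc <- which(field$bathymetry > 0, arr.ind = TRUE)
  w <- 1 / (1 + field$bathymetry[wc] / 30)   # nearshore bias
  pick <- sample(nrow(wc), config$n_stations, prob = w,
                 replace = config$n_stations > nrow(wc))
  data.frame(
    station_id = sprintf("st%02d", seq_len(config$n_stations)),
    lat = field$lat[wc[pick, 1]],
    lon = field$lon[wc[pick, 2]],
    array = paste0("A", 1 + (seq_len(config$n_stations) - 1) %/% 5))
}

#' Generate acoustic detections of a fish
#'
#' Daily detection probability at a station is the half-Gaussian range curve
#' `exp(-ln 2 * (d / r50)^2)` in the fish-station distance `d`, so that the
#' probability is exactly 0.5 at `r50`. A detected station-day yields 1-20
#' timestamped detections.
#'
#' @param truth A `truth_record`.
#' @param stations Station data frame (see [gen_stations()]).
#' @param config The [sim_config()].
#' @param seed Stream seed.
#' @return A [detection_set()].
#' @export
gen_detections <- function(truth, stations, config,
                           seed = derive_seed(config$seed, 71)) {
  set.seed(seed)
  r50_km <- config$r50_m / 1000
  rows <- list()
  for (t in seq_len(nrow(truth))) {
    if (!truth$alive[t]) next
    d <- haversine_km(truth$lat[t], truth$lon[t], stations$lat, stations$lon)
    p <- exp(-log(2) * (d / r50_km)^2)
    hit <- stats::runif(nrow(stations)) < p
    for (s in which(hit)) {
      nd <- sample(1:20, 1)
      secs <- sort(stats::runif(nd, 0, 86399))
      rows[[length(rows) + 1]] <- data.frame(
        tag_id = attr(truth, "tag_id"),
        timestamp = as.POSIXct(truth$date[t], tz = "UTC") + secs,
        station_id = stations$station_id[s])
    }
  }
  det <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(tag_id = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"),
               station_id = character(0))
  }
  detection_set(stations, det)
}

#' Generate a mark-recapture outcome for a fish
#'
#' Recapture day is geometric with the configured daily probability; the
#' reported position is the true position plus ~1 km of jitter.
#'
#' @param truth A `truth_record`.
#' @param config The [sim_config()].
#' @param seed Stream seed.
#' @return A [recapture_records()] data frame with 0 or 1 rows.
#' @export
gen_recaptures <- function(truth, config,
                           seed = derive_seed(config$seed, 89)) {
  set.seed(seed)
  empty <- recapture_records(data.frame(
    tag_id = character(0), release_date = as.Date(character(0)),
    release_lat = numeric(0), release_lon = numeric(0),
    recapture_date = as.Date(character(0)),
    recapture_lat = numeric(0), recapture_lon = numeric(0)))
  if (config$p_recapture <= 0) return(empty)
  day <- stats::rgeom(1, config$p_recapture) + 1
  if (day > nrow(truth)) return(empty)
  jit <- stats::rnorm(2, 0, 1 / 111.19)
  recapture_records(data.frame(
    tag_id = attr(truth, "tag_id"),
    release_date = truth$date[1],
    release_lat = truth$lat[1], release_lon = truth$lon[1],
    recapture_date = truth$date[day],
    recapture_lat = truth$lat[day] + jit[1],
    recapture_lon = truth$lon[day] + jit[2]))
}

#' Generate synthetic named areas for a field
#'
#' Splits the simulated domain into latitude bands standing in for the ICES
#' areas used in the analysis: North Sea (northernmost), English Channel,
#' Celtic Sea and Bay of Biscay (southernmost). The polygons are synthetic
#' rectangles, not real ICES divisions.
#'
#' @param field A `gridded_field`.
#' @param boundaries Decreasing latitudes separating the four bands.
#' @param cooling_sources Optional cooling-water source data frame.
#' @return An [area_set()].
#' @export
gen_area_set <- function(field, boundaries = NULL, cooling_sources = NULL) {
  rng_lat <- range(field$lat) + c(-1, 1) * 0.5
  rng_lon <- range(field$lon) + c(-1, 1) * 0.5
  if (is.null(boundaries)) {
    qs <- stats::quantile(rng_lat, c(0.65, 0.4, 0.2))
    boundaries <- as.numeric(qs)
  }
  stopifnot(length(boundaries) == 3, !is.unsorted(rev(boundaries)))
  band <- function(top, bottom) {
    list(lon = c(rng_lon[1], rng_lon[2], rng_lon[2], rng_lon[1]),
         lat = c(bottom, bottom, top, top))
  }
  area_set(list(
    "North Sea" = band(rng_lat[2], boundaries[1]),
    "English Channel" = band(boundaries[1], boundaries[2]),
    "Celtic Sea" = band(boundaries[2], boundaries[3]),
    "Bay of Biscay" = band(boundaries[3], rng_lat[1])
  ), cooling_sources = cooling_sources, check_overlap = FALSE)
}

#' Simulate a complete dataset
#'
#' Runs every generator with per-tag derived seeds: field, areas, stations,
#' `n_tags` trajectories with matching tag series, detections and recapture
#' outcomes.
#'
#' @param config A [sim_config()].
#' @param n_tags Number of fish.
#' @param outdir Optional directory; when given, all artifacts are written
#'   (CSV, NetCDF, GeoJSON, truth CSV).
#' @return List with `field`, `areas`, `stations`, `truths`, `series`,
#'   `detections`, `recaptures`, `config`.
#' @export
simulate_dataset <- function(config, n_tags = 1L, outdir = NULL) {
  field <- gen_field(config)
  areas <- gen_area_set(field, cooling_sources = {
    if (is.null(config$plume_sources)) NULL else
      data.frame(lat = config$plume_sources$lat,
                 lon = config$plume_sources$lon,
                 radius_km = config$plume_sources$radius_km)
  })
  stations <- gen_stations(config, field)
  truths <- list(); series <- list(); recs <- list()
  det_all <- NULL
  for (i in seq_len(n_tags)) {
    id <- sprintf("sim%02d", i)
    tr <- gen_trajectory(config, field, tag_id = id,
                         seed = derive_seed(config$seed, 1000 + 7 * i))
    se <- gen_tag_series(tr, field, config,
                         seed = derive_seed(config$seed, 2000 + 7 * i))
    de <- gen_detections(tr, stations, config,
                         seed = derive_seed(config$seed, 3000 + 7 * i))
    rc <- gen_recaptures(tr, config,
                         seed = derive_seed(config$seed, 4000 + 7 * i))
    truths[[id]] <- tr; series[[id]] <- se
    det_all <- if (is.null(det_all)) de$detections else
      rbind(det_all, de$detections)
    if (nrow(rc) > 0) recs[[id]] <- rc
  }
  detections <- detection_set(stations, det_all)
  recaptures <- if (length(recs) > 0) {
    recapture_records(do.call(rbind, lapply(recs, as.data.frame)))
  } else {
    gen_recaptures(truths[[1]], sim_config(seed = config$seed,
                                           p_recapture = 0))
  }
  out <- list(field = field, areas = areas, stations = stations,
              truths = truths, series = series, detections = detections,
              recaptures = recaptures, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_field_nc(field, file.path(outdir, "field.nc"))
    write_area_set(areas, file.path(outdir, "areas.geojson"))
    write_detections(detections, file.path(outdir, "detections.csv"),
                     file.path(outdir, "stations.csv"))
    write_recaptures(recaptures, file.path(outdir, "recaptures.csv"))
    for (id in names(series)) {
      write_tag_series(series[[id]], file.path(outdir, paste0(id, ".csv")))
      utils::write.csv(as.data.frame(truths[[id]]),
                       file.path(outdir, paste0(id, "_truth.csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  out
}
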