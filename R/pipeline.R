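# End-to-end orchestration: simulate -> preprocess -> geolocate -> metrics
# -> network, from a single (optionally YAML) configuration, writing every
# stage's artifacts and a run manifest.

#' Pipeline configuration
#'
#' @param outdir Output directory.
#' @param sim A [sim_config()].
#' @param hmm An [hmm_config()].
#' @param n_tags Number of simulated fish.
#' @param ec_split_lon English Channel east/west split longitude.
#' @param fidelity_horizon Fidelity horizon in days.
#' @param verbose Print stage progress.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = sim_config(), hmm = hmm_config(),
                            n_tags = 3L, ec_split_lon = -1.0,
                            fidelity_horizon = 180, verbose = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `outdir`, `n_tags`, `ec_split_lon`, `fidelity_horizon`,
#' plus `sim:` and `hmm:` sections whose keys are the arguments of
#' [sim_config()] and [hmm_config()].
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim %||% list()
  if (!is.null(simargs$start_date)) {
    simargs$start_date <- as.Date(simargs$start_date)
  }
  if (!is.null(simargs$trans)) {
    simargs$trans <- matrix(unlist(simargs$trans), 2, 2, byrow = TRUE)
  }
  hmmargs <- y$hmm %||% list()
  if (!is.null(hmmargs$D_range)) hmmargs$D_range <- unlist(hmmargs$D_range)
  pipeline_config(
    outdir = y$outdir %||% tempfile("basstrack_run_"),
    sim = do.call(sim_config, simargs),
    hmm = do.call(hmm_config, hmmargs),
    n_tags = y$n_tags %||% 3L,
    ec_split_lon = y$ec_split_lon %||% -1.0,
    fidelity_horizon = y$fidelity_horizon %||% 180,
    verbose = y$verbose %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Simulates a dataset, preprocesses every tag, runs the geolocation,
#' computes residency/fidelity/strategy metrics and the movement network,
#' writes all artifacts under `config$outdir` and a `manifest.json`
#' recording the seed, per-stage row counts and warnings.
#'
#' @param config A [pipeline_config()] or the path to a YAML file.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (config$verbose) message(...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$sim$seed, stages = list(), warnings = list())

  say("stage simulate: ", config$n_tags, " tags, ",
      config$sim$n_days, " days")
  sim <- simulate_dataset(config$sim, n_tags = config$n_tags,
                          outdir = file.path(config$outdir, "simulate"))
  manifest$stages$simulate <- list(
    n_tags = config$n_tags,
    n_detections = nrow(sim$detections$detections),
    n_recaptures = nrow(sim$recaptures))

  say("stage preprocess")
  det_qc <- qc_detections(sim$detections)
  cleans <- lapply(sim$series, preprocess_tag, field = sim$field)
  pp_dir <- file.path(config$outdir, "preprocess")
  dir.create(pp_dir, showWarnings = FALSE)
  for (id in names(cleans)) {
    utils::write.csv(as.data.frame(cleans[[id]]$daily),
                     file.path(pp_dir, paste0(id, "_daily.csv")),
                     row.names = FALSE)
  }
  manifest$stages$preprocess <- list(
    qc_removed = as.list(attr(det_qc, "qc_removed") %||%
                           c(array_singleton = 0, implausible_movement = 0)),
    usable_days = vapply(cleans, function(cl) nrow(usable_daily(cl)),
                         numeric(1)))

  say("stage geolocate")
  grid <- water_grid(sim$field)
  geo_dir <- file.path(config$outdir, "geolocate")
  dir.create(geo_dir, showWarnings = FALSE)
  tracks <- list()
  for (id in names(cleans)) {
    tr <- withCallingHandlers(
      geolocate_tag(cleans[[id]], sim$field, det = det_qc,
                    config = config$hmm, grid = grid),
      warning = function(w) {
        manifest$warnings[[length(manifest$warnings) + 1]] <<-
          paste0(id, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tracks[[id]] <- tr
    out <- cbind(tr$viterbi[, c("date", "lat", "lon")],
                 mean_lat = tr$mean$lat, mean_lon = tr$mean$lon,
                 modal_lat = tr$modal$lat, modal_lon = tr$modal$lon,
                 err_km = tr$err$err_km)
    utils::write.csv(out, file.path(geo_dir, paste0(id, "_track.csv")),
                     row.names = FALSE)
  }
  fitrep <- data.frame(
    tag_id = names(tracks),
    D = vapply(tracks, function(t) t$D, numeric(1)),
    loglik = vapply(tracks, function(t) t$loglik, numeric(1)),
    reliability = vapply(tracks, function(t) t$reliability, character(1)),
    median_err_km = vapply(tracks,
                           function(t) stats::median(t$err$err_km),
                           numeric(1)))
  utils::write.csv(fitrep, file.path(geo_dir, "fit_report.csv"),
                   row.names = FALSE)
  manifest$stages$geolocate <- list(
    reliability = as.list(table(fitrep$reliability)),
    D = as.list(stats::setNames(fitrep$D, fitrep$tag_id)))

  say("stage metrics")
  met_dir <- file.path(config$outdir, "metrics")
  dir.create(met_dir, showWarnings = FALSE)
  usable <- names(tracks)[vapply(tracks, function(t)
    t$reliability != "unreliable", logical(1))]
  area_tracks <- list(); strategies <- character(0)
  for (id in usable) {
    flags <- usable_daily(cleans[[id]])$cooling_water
    at <- assign_areas(tracks[[id]], sim$areas, cooling_flags = flags)
    area_tracks[[id]] <- at
    strategies[id] <- classify_strategy(at,
                                        ec_split_lon = config$ec_split_lon)
  }
  strat_tab <- strategy_summary(
    tracks[usable], strategies,
    dailies = lapply(cleans[usable], function(cl) usable_daily(cl)))
  utils::write.csv(strat_tab, file.path(met_dir, "strategies.csv"),
                   row.names = FALSE)
  res_tab <- do.call(rbind, lapply(names(sim$series), function(id) {
    residency_summary(det_qc, id, sim$truths[[id]]$date[1],
                      area_station_ids = det_qc$stations$station_id)
  }))
  utils::write.csv(res_tab, file.path(met_dir, "residency.csv"),
                   row.names = FALSE)
  rs <- recapture_stats(sim$recaptures)
  utils::write.csv(data.frame(bin = names(rs$bins), count = rs$bins),
                   file.path(met_dir, "recapture_bins.csv"),
                   row.names = FALSE)
  manifest$stages$metrics <- list(strategies = as.list(strategies),
                                  recapture_bins = as.list(rs$bins))

  say("stage network")
  groups <- stats::setNames(det_qc$stations$array,
                            det_qc$stations$station_id)
  net <- build_network(det_qc, groups)
  utils::write.csv(net$nodes, file.path(met_dir, "network_nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(net$edges, file.path(met_dir, "network_edges.csv"),
                   row.names = FALSE)
  manifest$stages$network <- list(n_nodes = nrow(net$nodes),
                                  total_edge_weight = sum(net$edges$count))

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("pipeline done in %.1f s", manifest$elapsed_s))
  invisible(list(sim = sim, cleans = cleans, detections = det_qc,
                 tracks = tracks, area_tracks = area_tracks,
                 strategies = strategies, strategy_table = strat_tab,
                 residency = res_tab, network = net, manifest = manifest))
}
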