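# Independent oracles and small fixtures used across the test files.

# Exhaustive enumeration over all cell paths: smoothed marginals, total
# likelihood, and the jointly most probable path (ties toward the
# lexicographically smallest path, i.e. lower cell indices).
# lik: T x n likelihood matrix; K: n x n transition matrix (or list per day,
# element t used for the transition into day t); prior: length-n day-1 prior.
enumerate_hmm <- function(lik, K, prior) {
  T_ <- nrow(lik); n <- ncol(lik)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  # expand.grid varies the FIRST factor fastest; reorder so column 1 is day 1
  # and paths are in lexicographic order of (day1, day2, ...)
  paths <- paths[, seq_len(T_), drop = FALSE]
  logp <- log(prior[paths[, 1]]) + log(lik[cbind(1, paths[, 1])])
  if (T_ > 1) {
    for (t in 2:T_) {
      Kt <- if (is.list(K)) K[[t]] else K
      logp <- logp + log(Kt[cbind(paths[, t - 1], paths[, t])]) +
        log(lik[cbind(t, paths[, t])])
    }
  }
  p <- exp(logp)
  tot <- sum(p)
  marg <- matrix(0, T_, n)
  for (t in seq_len(T_)) {
    marg[t, ] <- vapply(seq_len(n),
                        function(c) sum(p[paths[, t] == c]), numeric(1))
  }
  marg <- marg / tot
  # lexicographic tie-break: order paths so the first maximum is the
  # lexicographically smallest argmax
  ord <- do.call(order, lapply(seq_len(T_), function(t) paths[, t]))
  lp_ord <- logp[ord]
  best <- ord[which.max(lp_ord)]
  list(marginals = marg, loglik = log(tot),
       viterbi = as.integer(paths[best, ]),
       viterbi_logp = logp[best])
}

# A tiny all-water gridded field with constant bathymetry and temperature,
# handy for exercising the HMM machinery with handmade likelihoods.
flat_field <- function(nlat = 3, nlon = 3, n_days = 5, depth = 50,
                       lat0 = 0, lon0 = 0, dlat = 0.1, dlon = 0.1,
                       temp = 12) {
  lat <- lat0 + dlat * (seq_len(nlat) - 1)
  lon <- lon0 + dlon * (seq_len(nlon) - 1)
  dates <- as.Date("2015-01-01") + seq_len(n_days) - 1
  b <- matrix(depth, nlat, nlon)
  ts <- array(temp, c(nlat, nlon, n_days))
  gridded_field(lat, lon, dates, b, ts, ts)
}

# Random HMM instance on k cells x T days (positive random likelihoods and
# a random diffusion kernel from a flat field subgrid).
random_hmm_instance <- function(k, T_) {
  nlat <- max(2, ceiling(sqrt(k)))
  nlon <- max(2, ceiling(k / nlat))
  f <- flat_field(nlat = nlat, nlon = nlon, n_days = T_)
  g <- water_grid(f)
  keep <- seq_len(k)
  gk <- g
  gk$lat <- g$lat[keep]; gk$lon <- g$lon[keep]
  gk$bathy <- g$bathy[keep]; gk$dist <- g$dist[keep, keep, drop = FALSE]
  gk$n <- k
  D <- stats::runif(1, 5, 80)
  K <- movement_kernel(D, dt = 1, grid = gk)
  lik <- matrix(stats::runif(T_ * k, 0.05, 1), T_, k)
  prior <- stats::runif(k, 0.05, 1)
  prior <- prior / sum(prior)
  list(lik = lik, K = K, prior = prior, grid = gk)
}

# Build a tag_series directly from vectors (fixture shortcut).
make_series <- function(depth, temp = NULL, start = as.Date("2015-06-01"),
                        interval = 3600, tag_id = "fix1",
                        release_lat = 51, release_lon = 2) {
  n <- length(depth)
  if (is.null(temp)) temp <- rep(12, n)
  ts <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * interval
  tag_series(tag_id,
             data.frame(timestamp = ts, depth_m = depth, temp_c = temp),
             interval, release = list(date = start, lat = release_lat,
                                      lon = release_lon))
}
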