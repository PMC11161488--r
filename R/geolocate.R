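# Grid-based hidden Markov geolocation: observation likelihoods on water
# cells, diffusive movement kernels (optionally behaviour-switched),
# forward-backward smoothing, Viterbi decoding, diffusion-coefficient
# estimation and track reliability tiering.

#' Geolocation model configuration
#'
#' @param sigma_T Temperature observation sd (deg C). Default 0.5: the
#'   order of tag sensor accuracy plus sub-grid variability.
#' @param sigma_z Bathymetric tolerance sd (m). Default 4: how far the
#'   fish's daily maximum depth may exceed the cell's charted depth before
#'   the cell is effectively excluded.
#' @param sigma_d_m Detection kernel scale (m); the distance at which the
#'   unfloored detection likelihood is 0.5. Default 566, the measured 50%
#'   daily detection range for this tag type.
#' @param D_range Search range for the diffusion coefficient (km^2/day).
#' @param switching Use behaviour-switched kernels when the activity-state
#'   model converges.
#' @param terminal_anchor Use the recovery position (when present) as a
#'   final-day anchor. Off by default.
#' @param max_cells Refuse grids with more water cells than this.
#' @return Object of class `hmm_config`.
#' @export
hmm_config <- function(sigma_T = 0.5, sigma_z = 4, sigma_d_m = 566,
                       D_range = c(1, 100), switching = FALSE,
                       terminal_anchor = FALSE, max_cells = 10000L) {
  stopifnot(sigma_T > 0, sigma_z > 0, sigma_d_m > 0,
            length(D_range) == 2, all(D_range > 0),
            D_range[2] > D_range[1])
  structure(as.list(environment()), class = "hmm_config")
}

#' Water-cell geometry of a gridded field
#'
#' Indexes the water cells and precomputes their pairwise great-circle
#' distance matrix, used by the movement kernels. Build once per field and
#' pass to the kernel/geolocation functions to avoid recomputation.
#'
#' @param field A `gridded_field`.
#' @return Object of class `water_grid`: water-cell indices, coordinates,
#'   bathymetry, distance matrix (km) and mean cell diagonal (km).
#' @export
water_grid <- function(field) {
  w <- which(field$bathymetry > 0, arr.ind = TRUE)
  lat <- field$lat[w[, 1]]
  lon <- field$lon[w[, 2]]
  dist <- haversine_matrix_km(lat, lon, lat, lon)
  dlat_km <- haversine_km(field$lat[1], field$lon[1],
                          field$lat[2], field$lon[1])
  dlon_km <- haversine_km(mean(field$lat), field$lon[1],
                          mean(field$lat), field$lon[2])
  structure(list(idx = w, lat = lat, lon = lon,
                 bathy = field$bathymetry[w], dist = dist,
                 cell_diag_km = sqrt(dlat_km^2 + dlon_km^2),
                 n = nrow(w)),
            class = "water_grid")
}

#' Diffusive movement kernel over water cells
#'
#' Daily transition operator of a fish diffusing with coefficient `D`:
#' weight from cell i to cell j proportional to
#' `exp(-d_ij^2 / (4 D dt))`, truncated to 0 beyond
#' `truncation * sqrt(2 D dt)`, land excluded by construction, rows
#' renormalised to sum 1. The default truncation of 6 per-axis standard
#' deviations keeps the probability of forbidding a genuine daily
#' displacement negligible (~1e-8/day) while still bounding the support;
#' a 4-sd cut blocks a real step often enough (~1e-3/day) to make whole
#' true paths impossible under the joint decode.
#'
#' @param D Diffusion coefficient (km^2/day).
#' @param field A `gridded_field` (ignored when `grid` is supplied).
#' @param dt Time step in days (default 1).
#' @param grid Optional prebuilt [water_grid()].
#' @param truncation Support radius in units of `sqrt(2 D dt)`.
#' @return Dense row-stochastic matrix over water cells.
#' @export
movement_kernel <- function(D, field = NULL, dt = 1, grid = NULL,
                            truncation = 6) {
  stopifnot(D > 0, dt > 0)
  if (is.null(grid)) grid <- water_grid(field)
  r <- truncation * sqrt(2 * D * dt)
  K <- exp(-grid$dist^2 / (4 * D * dt))
  K[grid$dist > r] <- 0
  off_diag <- sum(K) - sum(diag(K))
  if (off_diag == 0 && grid$n > 1) {
    warning("movement_kernel: support smaller than one cell; ",
            "returning identity operator")
    return(diag(grid$n))
  }
  K / rowSums(K)
}

#' Bathymetric (maximum-depth) likelihood
#'
#' A cell is fully compatible when its charted depth is at least the fish's
#' daily maximum depth; shallower cells decay as a Gaussian in the depth
#' exceedance with sd `sigma_z`.
#'
#' @param obs One row of a `daily_obs` data frame (needs `max_depth`).
#' @param field A `gridded_field` (ignored when `grid` supplied).
#' @param sigma_z Tolerance sd (m).
#' @param grid Optional [water_grid()].
#' @return Likelihood vector over water cells.
#' @export
depth_likelihood <- function(obs, field = NULL, sigma_z = 4, grid = NULL) {
  if (is.null(grid)) grid <- water_grid(field)
  short <- pmax(obs$max_depth - grid$bathy, 0)
  exp(-short^2 / (2 * sigma_z^2))
}

#' Temperature likelihood
#'
#' The per-cell reference temperature interpolates linearly between the
#' surface and bottom layers at the fish's daily depth fraction (median
#' depth over local bathymetry, clamped to [0, 1]); the likelihood is
#' Gaussian in the difference to the tag's daily mean temperature.
#' Cooling-water flagged days carry no temperature information and return a
#' uniform likelihood.
#'
#' @param obs One row of a `daily_obs` data frame (needs `date`,
#'   `mean_temp`, `med_depth`, `cooling_water`).
#' @param field A `gridded_field` covering `obs$date`.
#' @param sigma_T Observation sd (deg C).
#' @param grid Optional [water_grid()].
#' @return Likelihood vector over water cells.
#' @export
temperature_likelihood <- function(obs, field, sigma_T = 0.5, grid = NULL) {
  if (is.null(grid)) grid <- water_grid(field)
  t <- match(as.Date(obs$date), field$dates)
  if (is.na(t)) stop("temperature_likelihood: date outside field range")
  if (isTRUE(obs$cooling_water)) return(rep(1, grid$n))
  ts <- field$temp_surface[, , t][grid$idx]
  tb <- field$temp_bottom[, , t][grid$idx]
  frac <- pmin(pmax(obs$med_depth / grid$bathy, 0), 1)
  ref <- ts + frac * (tb - ts)
  exp(-(obs$mean_temp - ref)^2 / (2 * sigma_T^2))
}

#' Acoustic detection likelihood
#'
#' Positive-information-only model: on days with at least one detection the
#' likelihood at a cell is the maximum over detecting stations of the range
#' curve `exp(-ln 2 * (d / sigma_d)^2)` floored at 1e-6; days without
#' detections are uninformative (uniform).
#'
#' @param date Calendar date.
#' @param det A QC'd [detection_set()].
#' @param tag_id Tag identifier.
#' @param field A `gridded_field` (ignored when `grid` supplied).
#' @param sigma_d_m Range scale in metres (0.5 probability at this
#'   distance).
#' @param grid Optional [water_grid()].
#' @param floor Likelihood floor.
#' @return Likelihood vector over water cells.
#' @export
detection_likelihood <- function(date, det, tag_id, field = NULL,
                                 sigma_d_m = 566, grid = NULL,
                                 floor = 1e-6) {
  if (is.null(grid)) grid <- water_grid(field)
  if (is.null(det)) return(rep(1, grid$n))
  d <- det$detections
  day_hits <- d$tag_id == tag_id &
    as.Date(d$timestamp, tz = "UTC") == as.Date(date)
  if (!any(day_hits)) return(rep(1, grid$n))
  sids <- unique(d$station_id[day_hits])
  st <- det$stations[match(sids, det$stations$station_id), ]
  sig_km <- sigma_d_m / 1000
  lik <- rep(0, grid$n)
  for (s in seq_len(nrow(st))) {
    dk <- haversine_km(grid$lat, grid$lon, st$lat[s], st$lon[s])
    lik <- pmax(lik, exp(-log(2) * (dk / sig_km)^2))
  }
  pmax(lik, floor)
}

# Normalise a likelihood matrix day-wise; relax all-zero days to uniform.
relax_zero_days <- function(lik) {
  zero <- rowSums(lik) == 0
  if (any(zero)) {
    warning(sum(zero), " day(s) with all-zero likelihood relaxed to uniform")
    lik[zero, ] <- 1
  }
  list(lik = lik, n_relaxed = sum(zero))
}

# kernels: a single matrix, or a list of length T whose element t is the
# kernel for the transition into day t (element 1 unused).
kernel_for <- function(kernels, t) {
  if (is.list(kernels)) kernels[[t]] else kernels
}

#' Forward-backward smoothing over the spatial grid
#'
#' Scaled forward recursion and backward smoothing of the spatial HMM. The
#' day-1 prior is multiplied into the first day's likelihood. Days whose
#' combined likelihood is all-zero are relaxed to uniform (with a warning)
#' rather than collapsing the model.
#'
#' @param lik `T x n` matrix of per-day combined likelihoods over water
#'   cells.
#' @param kernels A kernel matrix, or a list of length `T` giving the
#'   kernel for the transition into each day (element 1 unused).
#' @param prior Day-1 prior over water cells (e.g. a release point mass).
#' @return List: `post` (`T x n`, rows sum to 1), `loglik`, `n_relaxed`.
#' @export
forward_backward <- function(lik, kernels, prior) {
  T_ <- nrow(lik); n <- ncol(lik)
  stopifnot(length(prior) == n)
  rz <- relax_zero_days(lik); lik <- rz$lik
  alpha <- matrix(0, T_, n)
  cs <- numeric(T_)
  a <- prior * lik[1, ]
  if (sum(a) == 0) a <- lik[1, ]                     # anchor incompatible
  cs[1] <- sum(a)
  alpha[1, ] <- a / cs[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      K <- kernel_for(kernels, t)
      a <- as.numeric(crossprod(K, alpha[t - 1, ])) * lik[t, ]
      cs[t] <- sum(a)
      if (cs[t] == 0) {                              # unreachable evidence
        a <- as.numeric(crossprod(K, alpha[t - 1, ]))
        cs[t] <- sum(a)
      }
      alpha[t, ] <- a / cs[t]
    }
  }
  beta <- matrix(0, T_, n)
  beta[T_, ] <- 1
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      K <- kernel_for(kernels, t + 1)
      b <- as.numeric(K %*% (lik[t + 1, ] * beta[t + 1, ]))
      beta[t, ] <- b / cs[t + 1]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(post = post, loglik = sum(log(cs)), n_relaxed = rz$n_relaxed)
}

# Forward pass only; returns the log-likelihood (used in D estimation).
forward_loglik <- function(lik, kernels, prior) {
  T_ <- nrow(lik)
  rz <- relax_zero_days(lik); lik <- rz$lik
  a <- prior * lik[1, ]
  if (sum(a) == 0) a <- lik[1, ]
  ll <- log(sum(a))
  a <- a / sum(a)
  if (T_ > 1) {
    for (t in 2:T_) {
      K <- kernel_for(kernels, t)
      pred <- as.numeric(crossprod(K, a))
      anew <- pred * lik[t, ]
      s <- sum(anew)
      if (s == 0) {                     # evidence unreachable from support
        anew <- pred
        s <- sum(anew)
      }
      ll <- ll + log(s)
      a <- anew / s
    }
  }
  ll
}

#' Viterbi decoding of the most probable position sequence
#'
#' Jointly most probable water-cell sequence under the spatial HMM, ties
#' broken toward the lower cell index.
#'
#' @inheritParams forward_backward
#' @return List: `path` (cell indices per day), `logp` (joint log
#'   probability of the decoded path).
#' @export
viterbi_path <- function(lik, kernels, prior) {
  T_ <- nrow(lik); n <- ncol(lik)
  rz <- relax_zero_days(lik); lik <- rz$lik
  lprior <- log(prior)
  delta <- lprior + log(lik[1, ])
  if (all(delta == -Inf)) delta <- log(lik[1, ])
  back <- matrix(0L, T_, n)
  if (T_ > 1) {
    for (t in 2:T_) {
      lK <- log(kernel_for(kernels, t))
      M <- lK + delta                 # column recycling: M[i,j]=lK[i,j]+delta[i]
      tM <- t(M)
      arg <- max.col(tM, ties.method = "first")
      val <- tM[cbind(seq_len(n), arg)]
      back[t, ] <- arg
      delta <- val + log(lik[t, ])
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1) {
    for (t in (T_ - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  list(path = path, logp = max(delta))
}

#' Posterior mean and modal tracks
#'
#' Modal: per-day argmax cell (ties toward the lower index). Mean: per-day
#' posterior-weighted average of cell-centre coordinates (may fall between
#' cell centres but stays inside the convex hull of the support).
#'
#' @param post `T x n` smoothed posterior matrix.
#' @param grid The matching [water_grid()].
#' @return List of two data frames `mean` and `modal` with `lat`, `lon`
#'   per day (`modal` also has `cell`).
#' @export
mean_and_modal_tracks <- function(post, grid) {
  modal_cell <- max.col(post, ties.method = "first")
  list(
    mean = data.frame(lat = as.numeric(post %*% grid$lat),
                      lon = as.numeric(post %*% grid$lon)),
    modal = data.frame(lat = grid$lat[modal_cell],
                       lon = grid$lon[modal_cell], cell = modal_cell)
  )
}

#' Classify track reliability from daily error distances
#'
#' The daily error is the larger of the Viterbi-vs-mean and
#' Viterbi-vs-modal distances. A track is `reliable` when the median error
#' is below 50 km and the maximum below 120 km; tracks with median over 50
#' km or maximum between 120 and 240 km are usable for temporal (but not
#' spatial) interpretation (`temporal_only`); anything beyond 240 km
#' maximum is `unreliable`.
#'
#' @param median_err,max_err Median and maximum daily error in km.
#' @param median_thresh,max_thresh,hard_max Tier thresholds (km).
#' @return `"reliable"`, `"temporal_only"` or `"unreliable"`.
#' @export
reliability_tier <- function(median_err, max_err, median_thresh = 50,
                             max_thresh = 120, hard_max = 240) {
  if (median_err < median_thresh && max_err < max_thresh) return("reliable")
  if (max_err <= hard_max) return("temporal_only")
  "unreliable"
}

#' Validate a posterior track
#'
#' Computes (if absent) the daily Viterbi-vs-mean and Viterbi-vs-modal
#' distances and assigns the reliability tier (see [reliability_tier()]).
#'
#' @param track A `posterior_track`.
#' @return The track with `err` and `reliability` filled in.
#' @export
validate_track <- function(track) {
  stopifnot(inherits(track, "posterior_track"))
  em <- haversine_km(track$viterbi$lat, track$viterbi$lon,
                     track$mean$lat, track$mean$lon)
  eo <- haversine_km(track$viterbi$lat, track$viterbi$lon,
                     track$modal$lat, track$modal$lon)
  err <- pmax(em, eo)
  track$err <- data.frame(date = track$dates, err_mean_km = em,
                          err_mode_km = eo, err_km = err)
  track$reliability <- reliability_tier(stats::median(err), max(err))
  track
}

#' @export
print.posterior_track <- function(x, ...) {
  cat("<posterior_track>", x$tag_id, "|", length(x$dates), "days |",
      x$reliability, "\n")
  if (!is.null(x$D_high) && !is.na(x$D_high)) {
    cat(sprintf("  D_low = %.1f, D_high = %.1f km^2/day", x$D_low, x$D_high))
  } else {
    cat(sprintf("  D = %.1f km^2/day", x$D))
  }
  cat(sprintf(" | logLik = %.1f\n", x$loglik))
  if (!is.null(x$err)) {
    cat(sprintf("  error vs mean/mode: median %.1f km, max %.1f km\n",
                stats::median(x$err$err_km), max(x$err$err_km)))
  }
  invisible(x)
}

# Build the T x n combined likelihood matrix (depth * temperature *
# detection) for the usable days of a clean series.
build_likelihood <- function(daily, field, det, tag_id, config, grid) {
  T_ <- nrow(daily)
  lik <- matrix(0, T_, grid$n)
  for (t in seq_len(T_)) {
    obs <- daily[t, ]
    l <- depth_likelihood(obs, sigma_z = config$sigma_z, grid = grid) *
      temperature_likelihood(obs, field, sigma_T = config$sigma_T,
                             grid = grid)
    if (!is.null(det)) {
      l <- l * detection_likelihood(obs$date, det, tag_id,
                                    sigma_d_m = config$sigma_d_m,
                                    grid = grid)
    }
    lik[t, ] <- l
  }
  lik
}

release_prior <- function(release, grid) {
  d <- haversine_km(grid$lat, grid$lon, release$lat, release$lon)
  prior <- rep(0, grid$n)
  prior[which.min(d)] <- 1
  prior
}

# Golden-section maximisation of f over log-D in [lo, hi]; stops when the
# bracket ratio is below rel_tol.
golden_max_logD <- function(f, lo, hi, rel_tol = 0.05) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(exp(x1)); f2 <- f(exp(x2))
  while (exp(b - a) > 1 + rel_tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(exp(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(exp(x1))
    }
  }
  exp((a + b) / 2)
}

#' Estimate the diffusion coefficient and reconstruct the track
#'
#' Maximises the forward log-likelihood over `D` by golden-section search
#' on the log scale within `config$D_range` (5% relative tolerance). With
#' behavioural switching (decoded daily activity states supplied), a
#' two-parameter Nelder-Mead over `(D_low, D_high)` constrained to
#' `D_high >= D_low` refines from the single-D fit. Returns the full
#' posterior track at the fitted coefficient(s).
#'
#' @param clean A `clean_series` (>= 2 usable days; >= 30 recommended).
#' @param field The `gridded_field`.
#' @param det Optional QC'd [detection_set()].
#' @param config An [hmm_config()].
#' @param states Optional integer vector (1 = low, 2 = high) of decoded
#'   daily activity states enabling the behavioural switch.
#' @param grid Optional prebuilt [water_grid()].
#' @return A validated `posterior_track`.
#' @export
estimate_D <- function(clean, field, det = NULL, config = hmm_config(),
                       states = NULL, grid = NULL) {
  daily <- usable_daily(clean)
  if (nrow(daily) < 2) stop("estimate_D: need at least 2 usable days")
  if (is.null(grid)) grid <- water_grid(field)
  if (grid$n > config$max_cells) {
    stop("estimate_D: grid has ", grid$n, " water cells > max_cells")
  }
  lik <- build_likelihood(daily, field, det, clean$series$tag_id, config,
                          grid)
  prior <- release_prior(clean$series$release, grid)
  terminal <- NULL
  if (isTRUE(config$terminal_anchor) && !is.null(clean$series$recovery)) {
    terminal <- release_prior(clean$series$recovery, grid)
    lik[nrow(lik), ] <- lik[nrow(lik), ] * terminal
  }
  single_obj <- function(D) {
    K <- movement_kernel(D, dt = 1, grid = grid)
    forward_loglik(lik, K, prior)
  }
  D_hat <- golden_max_logD(single_obj, config$D_range[1], config$D_range[2])
  D_low <- NA_real_; D_high <- NA_real_
  kernels <- movement_kernel(D_hat, dt = 1, grid = grid)
  if (!is.null(states)) {
    stopifnot(length(states) == nrow(daily))
    switch_obj <- function(p) {
      Dl <- exp(p[1]); Dh <- exp(p[2])
      if (Dh < Dl || Dl < config$D_range[1] / 2 ||
          Dh > config$D_range[2] * 2) {
        return(1e10)
      }
      Kl <- movement_kernel(Dl, dt = 1, grid = grid)
      Kh <- movement_kernel(Dh, dt = 1, grid = grid)
      ks <- lapply(seq_len(nrow(lik)), function(t) {
        if (t == 1) Kl else if (states[t - 1] == 2) Kh else Kl
      })
      -forward_loglik(lik, ks, prior)
    }
    fit <- stats::optim(log(c(max(D_hat * 0.6, config$D_range[1]),
                              min(D_hat * 1.6, config$D_range[2]))),
                        switch_obj, method = "Nelder-Mead",
                        control = list(maxit = 60, reltol = 1e-3))
    D_low <- exp(fit$par[1]); D_high <- exp(fit$par[2])
    if (D_high < D_low) { tmp <- D_low; D_low <- D_high; D_high <- tmp }
    Kl <- movement_kernel(D_low, dt = 1, grid = grid)
    Kh <- movement_kernel(D_high, dt = 1, grid = grid)
    kernels <- lapply(seq_len(nrow(lik)), function(t) {
      if (t == 1) Kl else if (states[t - 1] == 2) Kh else Kl
    })
  }
  fb <- forward_backward(lik, kernels, prior)
  vt <- viterbi_path(lik, kernels, prior)
  tracks <- mean_and_modal_tracks(fb$post, grid)
  track <- structure(
    list(tag_id = clean$series$tag_id, dates = daily$date,
         grid = grid[c("lat", "lon", "cell_diag_km", "n")],
         post = fb$post,
         viterbi = data.frame(date = daily$date,
                              lat = grid$lat[vt$path],
                              lon = grid$lon[vt$path], cell = vt$path),
         mean = cbind(date = daily$date, tracks$mean),
         modal = cbind(date = daily$date, tracks$modal),
         loglik = fb$loglik, n_relaxed = fb$n_relaxed,
         D = D_hat, D_low = D_low, D_high = D_high,
         switching = !is.null(states), states = states,
         reliability = NA_character_, err = NULL),
    class = "posterior_track")
  validate_track(track)
}

#' Geolocate one tag end to end
#'
#' Convenience wrapper: optionally fits the activity-state model on the
#' usable daily series (behavioural switching is only engaged when that
#' model converges with well-separated states), then estimates the
#' diffusion coefficient(s) and reconstructs the track.
#'
#' @param clean A `clean_series` from [preprocess_tag()].
#' @param field The `gridded_field`.
#' @param det Optional QC'd [detection_set()].
#' @param config An [hmm_config()].
#' @param grid Optional prebuilt [water_grid()].
#' @return A validated `posterior_track` (with the `activity` fit attached
#'   when switching was requested).
#' @export
geolocate_tag <- function(clean, field, det = NULL, config = hmm_config(),
                          grid = NULL) {
  daily <- usable_daily(clean)
  states <- NULL
  act <- NULL
  if (isTRUE(config$switching) && nrow(daily) >= 30) {
    act <- fit_activity_states(daily)
    if (act$converged) states <- act$states
  }
  track <- estimate_D(clean, field, det = det, config = config,
                      states = states, grid = grid)
  track$activity <- act
  track
}
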