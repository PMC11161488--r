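test_that("movement kernel rows are stochastic and isotropic in open water", {
  f <- flat_field(nlat = 15, nlon = 15, dlat = 0.1, dlon = 0.1, lat0 = -0.7,
                  lon0 = 0)                       # equator: square cells
  g <- water_grid(f)
  for (D in c(2, 10, 50)) {
    K <- movement_kernel(D, dt = 1, grid = g)
    expect_equal(rowSums(K), rep(1, g$n), tolerance = 1e-12)
  }
  # interior cell: same weight one step N/S/E/W
  K <- movement_kernel(20, dt = 1, grid = g)
  ctr <- which(abs(g$lat - g$lat[which.min(abs(g$lat))]) < 1e-9 &
                 abs(g$lon - 0.7) < 1e-9)[1]
  nb <- function(dlat, dlon) {
    which(abs(g$lat - (g$lat[ctr] + dlat)) < 1e-9 &
            abs(g$lon - (g$lon[ctr] + dlon)) < 1e-9)[1]
  }
  w <- c(K[ctr, nb(0.1, 0)], K[ctr, nb(-0.1, 0)],
         K[ctr, nb(0, 0.1)], K[ctr, nb(0, -0.1)])
  expect_equal(max(w) / min(w), 1, tolerance = 1e-4)
})

test_that("kernel one-step displacement variance matches 2*D*dt per axis", {
  # large open grid at the equator so lat/lon steps are both ~11.1 km
  f <- flat_field(nlat = 41, nlon = 41, dlat = 0.1, dlon = 0.1,
                  lat0 = -2, lon0 = -2)
  g <- water_grid(f)
  for (D in c(30, 60)) {
    K <- movement_kernel(D, dt = 1, grid = g)
    ctr <- which(abs(g$lat) < 1e-9 & abs(g$lon) < 1e-9)
    w <- K[ctr, ]
    dlat_km <- haversine_km(g$lat, g$lon[ctr], g$lat[ctr], g$lon[ctr]) *
      sign(g$lat - g$lat[ctr] + 1e-15)
    var_lat <- sum(w * dlat_km^2)
    expect_equal(var_lat, 2 * D, tolerance = 0.1)
  }
})

test_that("kernel support below cell size degrades to the identity", {
  f <- flat_field(nlat = 6, nlon = 6, dlat = 0.5, dlon = 0.5)  # ~55 km cells
  g <- water_grid(f)
  expect_warning(K <- movement_kernel(0.5, dt = 1, grid = g), "identity")
  expect_equal(K, diag(g$n))
})

test_that("bathymetric likelihood is monotone and excludes shallow cells", {
  f <- flat_field(nlat = 4, nlon = 4)
  g <- water_grid(f)
  g$bathy <- seq(5, 80, length.out = g$n)
  obs0 <- data.frame(max_depth = 0)
  expect_equal(depth_likelihood(obs0, grid = g), rep(1, g$n))
  obs <- data.frame(max_depth = 35)
  lik <- depth_likelihood(obs, sigma_z = 4, grid = g)
  expect_true(all(diff(lik) >= -1e-12))          # non-decreasing in bathy
  expect_equal(lik[g$bathy >= 35], rep(1, sum(g$bathy >= 35)))
  # a cell 30 m too shallow is ruled out
  g_shallow <- g
  g_shallow$bathy <- rep(5, g$n)
  expect_lt(depth_likelihood(data.frame(max_depth = 35), sigma_z = 4,
                             grid = g_shallow)[1], 1e-10)
})

test_that("temperature likelihood follows the two-layer Gaussian model", {
  f <- flat_field(nlat = 3, nlon = 3, n_days = 2, depth = 50)
  f$temp_surface[, , 1] <- matrix(10:18, 3, 3)
  f$temp_bottom[, , 1] <- f$temp_surface[, , 1] - 2
  g <- water_grid(f)
  obs <- data.frame(date = f$dates[1], mean_temp = 13, med_depth = 25,
                    cooling_water = FALSE)
  lik <- temperature_likelihood(obs, f, sigma_T = 0.5, grid = g)
  # reference at half depth: surface - 1
  ref <- as.numeric(f$temp_surface[, , 1]) - 1
  expect_equal(which.max(lik), which(ref == 13))
  # likelihood ratio between two cells matches the Gaussian formula
  i <- which(ref == 12); j <- which(ref == 15)
  expect_equal(lik[i] / lik[j],
               exp((-(13 - 12)^2 + (13 - 15)^2) / (2 * 0.5^2)),
               tolerance = 1e-9)
  # cooling-water day: uniform
  obs$cooling_water <- TRUE
  expect_equal(temperature_likelihood(obs, f, grid = g), rep(1, g$n))
  obs$cooling_water <- FALSE
  obs$date <- as.Date("1999-01-01")
  expect_error(temperature_likelihood(obs, f, grid = g), "outside")
})

test_that("detection likelihood peaks at the station and is 0.5 at the range scale", {
  f <- flat_field(nlat = 9, nlon = 9, dlat = 0.05, dlon = 0.05)
  g <- water_grid(f)
  st <- data.frame(station_id = "s1", lat = f$lat[5], lon = f$lon[5],
                   array = "A")
  de <- data.frame(tag_id = "t1",
                   timestamp = as.POSIXct(f$dates[1], tz = "UTC") + 60,
                   station_id = "s1")
  det <- detection_set(st, de)
  lik <- detection_likelihood(f$dates[1], det, "t1", grid = g,
                              sigma_d_m = 566)
  at_station <- which(abs(g$lat - st$lat) < 1e-9 & abs(g$lon - st$lon) < 1e-9)
  expect_equal(which.max(lik), at_station)
  # day without detections: uniform
  expect_equal(detection_likelihood(f$dates[1] + 1, det, "t1", grid = g),
               rep(1, g$n))
  # unfloored curve value at d = sigma_d is exactly 0.5 (by construction)
  expect_equal(exp(-log(2) * (566 / 566)^2), 0.5)
  # and the implementation reproduces it at a cell ~sigma_d away
  g2 <- g
  g2$lat[1] <- st$lat + 566 / 111190; g2$lon[1] <- st$lon
  lik2 <- detection_likelihood(f$dates[1], det, "t1", grid = g2,
                               sigma_d_m = 566)
  expect_equal(lik2[1], 0.5, tolerance = 1e-4)
})

test_that("smoothed posteriors are uniform under uniform evidence", {
  # a doubly stochastic kernel preserves the uniform distribution
  K <- matrix(1 / 9, 9, 9)
  lik <- matrix(1, 4, 9)
  prior <- rep(1 / 9, 9)
  fb <- forward_backward(lik, K, prior)
  expect_equal(fb$post, matrix(1 / 9, 4, 9), tolerance = 1e-12)
})

test_that("smoothing and Viterbi match exhaustive enumeration on small instances", {
  set.seed(41)
  for (rep in 1:25) {
    k <- sample(2:9, 1); T_ <- sample(2:5, 1)
    inst <- random_hmm_instance(k, T_)
    fb <- forward_backward(inst$lik, inst$K, inst$prior)
    vt <- viterbi_path(inst$lik, inst$K, inst$prior)
    oracle <- enumerate_hmm(inst$lik, inst$K, inst$prior)
    expect_equal(fb$post, oracle$marginals, tolerance = 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(vt$path, oracle$viterbi)
    expect_true(all(abs(rowSums(fb$post) - 1) < 1e-9))
  }
})

test_that("point-mass evidence pins both smoother and Viterbi", {
  inst <- random_hmm_instance(8, 5)
  cells <- c(1, 2, 4, 4, 7)
  lik <- matrix(0, 5, 8)
  lik[cbind(1:5, cells)] <- 1
  prior <- rep(1 / 8, 8)
  fb <- forward_backward(lik, inst$K, prior)
  vt <- viterbi_path(lik, inst$K, prior)
  expect_equal(max.col(fb$post), cells)
  expect_equal(vt$path, cells)
  expect_equal(fb$post[cbind(1:5, cells)], rep(1, 5), tolerance = 1e-12)
})

test_that("log-likelihood is invariant to uniform rescaling of a day's likelihood", {
  inst <- random_hmm_instance(7, 4)
  fb1 <- forward_backward(inst$lik, inst$K, inst$prior)
  lik2 <- inst$lik
  lik2[3, ] <- lik2[3, ] * 37
  fb2 <- forward_backward(lik2, inst$K, inst$prior)
  expect_equal(fb2$loglik - fb1$loglik, log(37), tolerance = 1e-10)
  expect_equal(fb2$post, fb1$post, tolerance = 1e-12)
})

test_that("all-zero likelihood days are relaxed to uniform with a warning", {
  inst <- random_hmm_instance(6, 4)
  lik <- inst$lik
  lik[2, ] <- 0
  expect_warning(fb <- forward_backward(lik, inst$K, inst$prior), "relaxed")
  expect_equal(fb$n_relaxed, 1L)
  expect_true(all(abs(rowSums(fb$post) - 1) < 1e-9))
})

test_that("single-day Viterbi is the argmax of the prior-weighted likelihood", {
  lik <- matrix(c(0.1, 0.9, 0.3), 1, 3)
  prior <- c(0.5, 0.1, 0.4)
  vt <- viterbi_path(lik, diag(3), prior)
  expect_equal(vt$path, which.max(lik[1, ] * prior))
})

test_that("Viterbi ties break toward the lower cell index", {
  lik <- matrix(1, 3, 4)
  K <- matrix(0.25, 4, 4)
  prior <- rep(0.25, 4)
  vt <- viterbi_path(lik, K, prior)
  expect_equal(vt$path, c(1L, 1L, 1L))
})

test_that("mean and modal tracks behave on point-mass and bimodal posteriors", {
  f <- flat_field(nlat = 5, nlon = 5)
  g <- water_grid(f)
  post <- matrix(0, 2, g$n)
  post[1, 7] <- 1
  post[2, c(3, 23)] <- 0.5
  mm <- mean_and_modal_tracks(post, g)
  expect_equal(mm$modal$lat[1], g$lat[7])
  expect_equal(mm$mean$lat[1], g$lat[7])
  expect_equal(mm$mean$lat[2], mean(g$lat[c(3, 23)]))
  expect_equal(mm$modal$cell[2], 3)              # tie impossible here; argmax
  # mean track stays in the convex hull of the support
  expect_true(mm$mean$lat[2] >= min(g$lat[c(3, 23)]) &&
                mm$mean$lat[2] <= max(g$lat[c(3, 23)]))
})

test_that("reliability tiers reproduce the published thresholds", {
  expect_equal(reliability_tier(4.61, 116.0), "reliable")
  expect_equal(reliability_tier(60, 100), "temporal_only")
  expect_equal(reliability_tier(30, 150), "temporal_only")
  expect_equal(reliability_tier(30, 300), "unreliable")
  expect_equal(reliability_tier(49.9, 119.9), "reliable")
  expect_equal(reliability_tier(50, 119.9), "temporal_only")
})

test_that("fitted D is a local optimum and recovers the truth's order of magnitude", {
  cfg <- sim_config(seed = 43, nlat = 25, nlon = 25, n_days = 60,
                    D_low = 30, D_high = 30)
  f <- gen_field(cfg)
  tr <- gen_trajectory(cfg, f)
  cl <- preprocess_tag(gen_tag_series(tr, f, cfg), field = f)
  g <- water_grid(f)
  track <- estimate_D(cl, f, config = hmm_config(sigma_T = 0.15), grid = g)
  lik <- basstrack:::build_likelihood(usable_daily(cl), f, NULL, "sim1",
                                      hmm_config(sigma_T = 0.15), g)
  prior <- basstrack:::release_prior(cl$series$release, g)
  ll_at <- function(D) basstrack:::forward_loglik(
    lik, movement_kernel(D, dt = 1, grid = g), prior)
  expect_gte(ll_at(track$D), ll_at(track$D / 2))
  expect_gte(ll_at(track$D), ll_at(track$D * 2))
  expect_gt(track$D, 5)
  expect_lt(track$D, 100)
})

test_that("behavioural switching keeps D_high at or above D_low", {
  cfg <- sim_config(seed = 44, nlat = 20, nlon = 20, n_days = 60,
                    D_low = 3, D_high = 40)
  f <- gen_field(cfg)
  tr <- gen_trajectory(cfg, f)
  cl <- preprocess_tag(gen_tag_series(tr, f, cfg), field = f)
  track <- geolocate_tag(cl, f,
                         config = hmm_config(sigma_T = 0.15,
                                             switching = TRUE))
  if (track$switching) {
    expect_gte(track$D_high, track$D_low)
  } else {
    expect_true(is.na(track$D_high))
  }
})

test_that("geolocation pins a stationary fish with tight evidence", {
  # a fish that never moves, on a field with a strong gradient: the track
  # should sit on the true cell almost every day
  cfg <- sim_config(seed = 45, nlat = 15, nlon = 15, n_days = 40,
                    D_low = 1, D_high = 1)
  f <- gen_field(cfg)
  tr <- gen_trajectory(cfg, f)
  cl <- preprocess_tag(gen_tag_series(tr, f, cfg), field = f)
  track <- geolocate_tag(cl, f, config = hmm_config(sigma_T = 0.15))
  err <- haversine_km(track$viterbi$lat, track$viterbi$lon, tr$lat, tr$lon)
  expect_lt(stats::median(err), 3 * track$grid$cell_diag_km)
})
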