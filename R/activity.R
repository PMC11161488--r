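# Two-state Gaussian hidden Markov model on the log vertical activity
# index, fitted by EM. Decoded states drive the behavioural switch of the
# movement model: low-activity days get the small diffusion coefficient,
# high-activity days the large one.

#' Fit daily activity states
#'
#' Fits a 2-state Gaussian HMM to `log(1 + activity_index)` by
#' expectation-maximisation (at most `max_iter` iterations, stopping when
#' the log-likelihood improves by less than `tol`), decodes states by
#' Viterbi, and labels the state with the larger mean "high". The fit is
#' declared unconverged -- and behavioural switching should then stay off --
#' when EM fails, or when the state means are separated by less than one
#' pooled standard deviation (an automated stand-in for a visual
#' reliability check of the state assignment).
#'
#' @param daily A `daily_obs` data frame (>= 30 rows with a defined
#'   activity index).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @return Object of class `activity_states`: `states` (1 = low, 2 = high,
#'   per row of `daily`; days with undefined activity inherit the previous
#'   state), `mu`, `sigma`, `trans`, `init`, `loglik`, `separation`
#'   (mean gap in pooled sds), `converged`.
#' @export
fit_activity_states <- function(daily, max_iter = 500, tol = 1e-6) {
  x_all <- log1p(daily$activity_index)
  ok <- is.finite(x_all)
  x <- x_all[ok]
  if (length(x) < 30) {
    stop("fit_activity_states: need >= 30 days with defined activity")
  }
  degenerate <- function() {
    structure(list(states = rep(1L, nrow(daily)),
                   mu = c(mean(x), mean(x)),
                   sigma = c(stats::sd(x), stats::sd(x)),
                   trans = matrix(0.5, 2, 2), init = c(1, 0),
                   loglik = NA_real_, separation = 0, converged = FALSE),
              class = "activity_states")
  }
  if (stats::sd(x) == 0) return(degenerate())
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-0.1, 0.1)
  sig <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  trans <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  init <- c(0.5, 0.5)
  ll_old <- -Inf
  converged_em <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- cbind(stats::dnorm(x, mu[1], sig[1]),
                  stats::dnorm(x, mu[2], sig[2]))
    dens <- pmax(dens, 1e-300)
    # scaled forward-backward over the two states
    alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2); cs <- numeric(n)
    a <- init * dens[1, ]; cs[1] <- sum(a); alpha[1, ] <- a / cs[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% trans) * dens[t, ]
      cs[t] <- sum(a); alpha[t, ] <- a / cs[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1) {
      beta[t, ] <- (trans %*% (dens[t + 1, ] * beta[t + 1, ])) / cs[t + 1]
    }
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi <- matrix(0, 2, 2)
    for (t in 2:n) {
      m <- (alpha[t - 1, ] %o% (dens[t, ] * beta[t, ])) * trans / cs[t]
      xi <- xi + m
    }
    ll <- sum(log(cs))
    # M-step
    init <- gamma[1, ]
    trans <- xi / rowSums(xi)
    for (k in 1:2) {
      w <- gamma[, k]
      mu[k] <- sum(w * x) / sum(w)
      sig[k] <- sqrt(sum(w * (x - mu[k])^2) / sum(w))
      sig[k] <- max(sig[k], 1e-4)
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged_em <- TRUE
      break
    }
    ll_old <- ll
  }
  # order states: 1 = low activity, 2 = high
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]
  trans <- trans[ord, ord, drop = FALSE]
  init <- init[ord]
  pooled <- sqrt(mean(sig^2))
  separation <- (mu[2] - mu[1]) / pooled
  # Viterbi decoding
  ldens <- cbind(stats::dnorm(x, mu[1], sig[1], log = TRUE),
                 stats::dnorm(x, mu[2], sig[2], log = TRUE))
  ltr <- log(pmax(trans, 1e-300))
  delta <- log(pmax(init, 1e-300)) + ldens[1, ]
  back <- matrix(0L, n, 2)
  for (t in 2:n) {
    for (k in 1:2) {
      v <- delta + ltr[, k]
      back[t, k] <- which.max(v)

    }
    delta <- vapply(1:2, function(k) max(delta + ltr[, k]), numeric(1)) +
      ldens[t, ]
  }
  st <- integer(n)
  st[n] <- which.max(delta)
  for (t in (n - 1):1) st[t] <- back[t + 1, st[t + 1]]
  states <- rep(NA_integer_, nrow(daily))
  states[ok] <- st
  # undefined-activity days inherit the previous decoded state
  for (t in seq_along(states)) {
    if (is.na(states[t])) states[t] <- if (t == 1) 1L else states[t - 1]
  }
  structure(list(states = states, mu = mu, sigma = sig, trans = trans,
                 init = init, loglik = ll,
                 separation = separation,
                 converged = converged_em && separation >= 1),
            class = "activity_states")
}

#' @export
print.activity_states <- function(x, ...) {
  cat("<activity_states> converged:", x$converged,
      sprintf("| separation %.2f pooled sd\n", x$separation))
  cat(sprintf("  low:  mu %.2f sd %.2f | high: mu %.2f sd %.2f\n",
              x$mu[1], x$sigma[1], x$mu[2], x$sigma[2]))
  cat(sprintf("  P(stay low) %.2f, P(stay high) %.2f | high days: %d\n",
              x$trans[1, 1], x$trans[2, 2], sum(x$states == 2L)))
  invisible(x)
}
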