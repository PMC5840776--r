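# Two-state persistent random-walk model of single-cell migration:
# simulation, summary statistics, marginal step-displacement density,
# hidden-Markov EM fitting and state decoding.
#
# Each migration state has three parameters: mean speed mu_s, speed SD
# sigma_s (speed ~ Normal truncated at 0) and orientation-change SD
# sigma_theta (turning angle ~ wrapped Normal, zero mean). A fourth
# parameter alpha is the stationary fraction of time spent in state 1;
# state switching is a first-order Markov chain with mean-run-length
# scale `dwell` (dwell = 1 recovers a memoryless mixture).

#' Per-state migration parameters
#'
#' @param mu_s Mean speed (\eqn{\mu}m/min, >= 0).
#' @param sigma_s Speed SD (\eqn{\mu}m/min, >= 0); speeds are Normal
#'   truncated at 0, so the realized mean speed exceeds `mu_s` when
#'   truncation bites.
#' @param sigma_theta SD of the per-step orientation change (radians,
#'   >= 0); 0 = perfectly persistent, large values approach an
#'   uncorrelated random walk.
#' @return Object of class `state_params`.
#' @export
state_params <- function(mu_s, sigma_s, sigma_theta) {
  for (v in c(mu_s, sigma_s, sigma_theta)) stopifnot_scalar(v)
  if (mu_s < 0 || sigma_s < 0 || sigma_theta < 0)
    stop("state parameters must be nonnegative", call. = FALSE)
  structure(list(mu_s = mu_s, sigma_s = sigma_s, sigma_theta = sigma_theta),
            class = "state_params")
}

#' Two-state model parameters
#'
#' @param state1,state2 [state_params()] for the two states. By
#'   convention state 1 is the slower state.
#' @param alpha Stationary fraction of time in state 1 (0--1).
#' @param dwell Mean-dwell scale (>= 1) of the switching chain: the
#'   per-step switching probabilities are `(1 - alpha) / dwell` out of
#'   state 1 and `alpha / dwell` out of state 2, so the stationary
#'   distribution is `(alpha, 1 - alpha)` for any dwell, and `dwell = 1`
#'   is the memoryless mixture.
#' @return Object of class `model_params`.
#' @export
model_params <- function(state1, state2, alpha, dwell = 10) {
  if (!inherits(state1, "state_params") || !inherits(state2, "state_params"))
    stop("'state1' and 'state2' must be state_params objects", call. = FALSE)
  stopifnot_scalar(alpha); stopifnot_scalar(dwell)
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]", call. = FALSE)
  if (dwell < 1) stop("'dwell' must be >= 1", call. = FALSE)
  structure(list(state1 = state1, state2 = state2, alpha = alpha,
                 dwell = dwell), class = "model_params")
}

#' Transition matrix of the switching chain
#'
#' @param params A [model_params()] object.
#' @return 2x2 row-stochastic matrix with stationary distribution
#'   `(alpha, 1 - alpha)`.
#' @export
transition_matrix <- function(params) {
  p12 <- (1 - params$alpha) / params$dwell
  p21 <- params$alpha / params$dwell
  matrix(c(1 - p12, p21, p12, 1 - p21), 2, 2)
}

#' A single-cell track
#'
#' @param positions Numeric n x 2 matrix of (x, y) positions in
#'   \eqn{\mu}m, time-ordered; n >= 3.
#' @param dt Frame interval in minutes (> 0).
#' @return Object of class `cell_track`.
#' @export
cell_track <- function(positions, dt) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) < 3L || any(!is.finite(positions)))
    stop("'positions' must be a finite n x 2 matrix with n >= 3", call. = FALSE)
  stopifnot_scalar(dt)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  structure(list(positions = unname(positions), dt = dt), class = "cell_track")
}

#' Simulate tracks from the two-state model
#'
#' The hidden state follows the two-state Markov chain started from its
#' stationary distribution. The initial orientation is uniform; at each
#' step the orientation is the previous orientation plus wrapped-Normal
#' noise with the SD of the step's state, the speed is drawn from the
#' state's zero-truncated Normal, and the displacement is
#' `speed * dt * (cos theta, sin theta)`.
#'
#' @param params A [model_params()] object.
#' @param n_cells Number of tracks.
#' @param n_steps Number of steps per track (>= 2; tracks have
#'   `n_steps + 1` positions).
#' @param dt Frame interval in minutes.
#' @param seed RNG seed.
#' @return List with `tracks` (list of [cell_track()]) and `states`
#'   (list of integer vectors, the true state of each step).
#' @export
simulate_tracks <- function(params, n_cells, n_steps, dt, seed = 1) {
  if (!inherits(params, "model_params")) stop("invalid 'params'", call. = FALSE)
  if (n_steps < 2) stop("'n_steps' must be >= 2", call. = FALSE)
  stopifnot_scalar(dt); if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  A <- transition_matrix(params)
  mu <- c(params$state1$mu_s, params$state2$mu_s)
  sig <- c(params$state1$sigma_s, params$state2$sigma_s)
  sth <- c(params$state1$sigma_theta, params$state2$sigma_theta)
  with_seed(seed, {
    tracks <- states <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      s <- integer(n_steps)
      s[1] <- if (runif(1) < params$alpha) 1L else 2L
      if (n_steps > 1) {
        u <- runif(n_steps - 1)
        for (t in 2:n_steps) s[t] <- if (u[t - 1] < A[s[t - 1], 1]) 1L else 2L
      }
      turn <- rnorm(n_steps, 0, sth[s])
      theta <- cumsum(c(runif(1, -pi, pi), turn[-1]))
      speed <- rtnorm0(n_steps, mu[s], pmax(sig[s], 1e-12))
      speed[sig[s] == 0] <- mu[s][sig[s] == 0]
      step <- cbind(speed * dt * cos(theta), speed * dt * sin(theta))
      pos <- rbind(c(0, 0), apply(step, 2, cumsum))
      tracks[[i]] <- cell_track(pos, dt)
      states[[i]] <- s
    }
    list(tracks = tracks, states = states)
  })
}

#' Per-step statistics of a track
#'
#' @param track A [cell_track()].
#' @return Data frame with one row per step: `speed`
#'   (\eqn{\mu}m/min), `dx`, `dy` (\eqn{\mu}m), `heading` (radians) and
#'   `turn` (signed orientation change from the previous step, wrapped
#'   to (-pi, pi]; `NA` for the first step and wherever a zero-length
#'   displacement makes the angle undefined, flagged in `turn_ok`).
#' @export
step_stats <- function(track) {
  if (!inherits(track, "cell_track")) stop("not a cell_track", call. = FALSE)
  p <- track$positions
  d <- diff(p)
  len <- sqrt(rowSums(d^2))
  heading <- ifelse(len > 0, atan2(d[, 2], d[, 1]), NA_real_)
  turn <- c(NA_real_, wrap_angle(diff(heading)))
  data.frame(speed = len / track$dt, dx = d[, 1], dy = d[, 2],
             heading = heading, turn = turn, turn_ok = !is.na(turn))
}

#' Directional variance over a time lag
#'
#' The circular variance `1 - |mean unit vector|` of orientation changes
#' over the given lag: 0 for perfectly persistent motion, approaching 1
#' for uncorrelated directions.
#'
#' @param tracks A [cell_track()] or list of them (pooled).
#' @param lag Time lag in minutes; must be a positive integer multiple
#'   of the frame interval.
#' @return Dimensionless value in \[0, 1\].
#' @export
directional_variance <- function(tracks, lag) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  deltas <- unlist(lapply(tracks, function(tr) {
    k <- lag / tr$dt
    if (abs(k - round(k)) > 1e-9 || k < 1)
      stop("'lag' must be a positive integer multiple of dt", call. = FALSE)
    k <- as.integer(round(k))
    h <- step_stats(tr)$heading
    n <- length(h)
    if (n <= k) return(numeric(0))
    d <- h[(1 + k):n] - h[1:(n - k)]
    d[!is.na(d)]
  }))
  if (length(deltas) < 2L)
    stop("fewer than 2 usable orientation changes", call. = FALSE)
  1 - sqrt(mean(cos(deltas))^2 + mean(sin(deltas))^2)
}

#' Marginal density of the per-frame x-displacement
#'
#' Under the model, a step's x-displacement is `speed * dt * cos(theta)`
#' with theta uniform at stationarity, so each state contributes
#' \deqn{f_k(\Delta x) = \int_{|\Delta x|/dt}^{\infty}
#'   g_k(s) \frac{ds}{\pi\sqrt{(s\,dt)^2 - \Delta x^2}}}
#' with \eqn{g_k} the state's zero-truncated Normal speed density (the
#' arcsine projection kernel), and the marginal is the
#' alpha-weighted mixture. In the `sigma_s -> 0` limit the density is
#' the closed-form arcsine law on `(-mu_s dt, mu_s dt)`.
#'
#' @param params A [model_params()] or [state_params()] object.
#' @param dt Frame interval in minutes.
#' @return Object of class `dx_density` with vectorized functions
#'   `pdf(x)` and `cdf(x)` (x in \eqn{\mu}m) and the support half-width
#'   `xmax`.
#' @export
marginal_dx_density <- function(params, dt) {
  stopifnot_scalar(dt); if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (inherits(params, "state_params"))
    params <- model_params(params, params, alpha = 1)
  if (!inherits(params, "model_params")) stop("invalid 'params'", call. = FALSE)
  comp <- list(params$state1, params$state2)
  w <- c(params$alpha, 1 - params$alpha)

  comp_pdf <- function(x, sp) {
    mu <- sp$mu_s; sig <- sp$sigma_s
    if (sig < 1e-8) {                       # arcsine law
      if (mu * dt < 1e-12)                  # point mass at 0
        return(ifelse(x == 0, Inf, 0))
      r <- mu * dt
      return(ifelse(abs(x) < r, 1 / (pi * sqrt(r^2 - x^2)), 0))
    }
    smax <- mu + 10 * sig
    vapply(x, function(xi) {
      a <- max(abs(xi) / dt, 1e-12 * smax)
      if (a >= smax) return(0)
      U <- acosh(smax / a)
      integrate(function(u) dtnorm0(a * cosh(u), mu, sig), 0, U,
                rel.tol = 1e-9, abs.tol = 1e-12)$value / (pi * dt)
    }, numeric(1))
  }
  comp_cdf <- function(x, sp) {
    mu <- sp$mu_s; sig <- sp$sigma_s
    if (sig < 1e-8) {
      if (mu * dt < 1e-12) return(as.numeric(x >= 0))
      return(1 - acos(pmin(pmax(x / (mu * dt), -1), 1)) / pi)
    }
    smax <- mu + 10 * sig
    h <- function(c) 1 - acos(pmin(pmax(c, -1), 1)) / pi
    vapply(x, function(xi) {
      if (xi >= smax * dt) return(1)
      if (xi <= -smax * dt) return(0)
      integrate(function(s) dtnorm0(s, mu, sig) * h(xi / (s * dt)),
                0, smax, rel.tol = 1e-9, abs.tol = 1e-12)$value
    }, numeric(1))
  }
  xmax <- max(vapply(comp, function(sp) (sp$mu_s + 10 * sp$sigma_s) * dt,
                     numeric(1)))
  structure(list(
    pdf = function(x) w[1] * comp_pdf(x, comp[[1]]) + w[2] * comp_pdf(x, comp[[2]]),
    cdf = function(x) w[1] * comp_cdf(x, comp[[1]]) + w[2] * comp_cdf(x, comp[[2]]),
    xmax = xmax, dt = dt, params = params), class = "dx_density")
}

#' Kolmogorov--Smirnov distance between a sample and a model CDF
#'
#' Evaluates the CDF on a fine grid (the model CDFs here are smooth) and
#' interpolates at the sample points.
#'
#' @param x Numeric sample.
#' @param cdf Vectorized CDF function.
#' @param grid_n Number of grid points for interpolation.
#' @return The KS statistic `sup |F_n - F|`.
#' @export
ks_statistic <- function(x, cdf, grid_n = 4001) {
  x <- sort(x)
  n <- length(x)
  pad <- diff(range(x)) * 0.01 + 1e-9
  grid <- seq(x[1] - pad, x[n] + pad, length.out = grid_n)
  Fg <- cdf(grid)
  Fx <- approx(grid, Fg, xout = x)$y
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

## ---- HMM internals -------------------------------------------------------

# Flatten tracks to per-step emissions: speeds, turns (NA where undefined),
# and track lengths for the forward-backward pass.
prep_steps <- function(tracks) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  stats <- lapply(tracks, step_stats)
  lens <- vapply(stats, nrow, integer(1))
  speed <- unlist(lapply(stats, `[[`, "speed"))
  turn <- unlist(lapply(stats, `[[`, "turn"))
  if (all(speed == 0))
    stop("degenerate tracks: all displacements are zero", call. = FALSE)
  list(speed = speed, turn = turn, lens = lens,
       starts = cumsum(c(1L, lens[-length(lens)])))
}

# log emission densities, one column per state
emission_logdens <- function(steps, mu, sig, sth) {
  n <- length(steps$speed)
  out <- matrix(0, n, length(mu))
  ok <- !is.na(steps$turn)
  for (k in seq_along(mu)) {
    out[, k] <- dtnorm0(steps$speed, mu[k], sig[k], log = TRUE)
    out[ok, k] <- out[ok, k] + dwrapnorm(steps$turn[ok], sth[k], log = TRUE)
  }
  out
}

# Scaled forward-backward for one track segment. logB: T x K.
forward_backward <- function(logB, A, pi0) {
  Tn <- nrow(logB); K <- ncol(logB)
  m <- apply(logB, 1, max)
  B <- exp(logB - m)
  af <- matrix(0, Tn, K); cs <- numeric(Tn)
  a <- pi0 * B[1, ]; cs[1] <- sum(a); af[1, ] <- a / cs[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (af[t - 1, ] %*% A)[1, ] * B[t, ]
    cs[t] <- sum(a); af[t, ] <- a / cs[t]
  }
  bw <- matrix(0, Tn, K); bw[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    bw[t, ] <- (A %*% (B[t + 1, ] * bw[t + 1, ]))[, 1] / cs[t + 1]
  gamma <- af * bw
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  if (Tn > 1) for (t in 2:Tn) {
    x <- (af[t - 1, ] %o% (B[t, ] * bw[t, ])) * A
    xi <- xi + x / sum(x)
  }
  list(loglik = sum(log(cs)) + sum(m), gamma = gamma, xi = xi)
}

# Weighted truncated-Normal MLE from sufficient statistics.
tnorm_mle <- function(Sw, S1, S2) {
  mu0 <- S1 / Sw
  sig0 <- sqrt(max(S2 / Sw - mu0^2, 1e-8))
  # negative weighted log-likelihood (constants dropped):
  #   Sw log sigma + sum w (s - mu)^2 / (2 sigma^2) + Sw log Phi(mu/sigma)
  nll <- function(p) {
    mu <- p[1]; sig <- exp(p[2])
    Sw * log(sig) + (S2 - 2 * mu * S1 + mu^2 * Sw) / (2 * sig^2) +
      Sw * pnorm(mu / sig, log.p = TRUE)
  }
  fit <- optim(c(max(mu0, 0), log(sig0)), nll, method = "L-BFGS-B",
               lower = c(0, log(1e-6)), upper = c(Inf, log(1e3)),
               control = list(maxit = 500, factr = 1e4))
  c(mu = fit$par[1], sigma = max(exp(fit$par[2]), 1e-6))
}

# Weighted wrapped-Normal sigma: circular-moment start, 1-D refinement.
wrapnorm_mle <- function(theta, w) {
  s0 <- wrapnorm_sigma_moment(theta, w)
  f <- function(sig) -sum(w * dwrapnorm(theta, sig, log = TRUE))
  lo <- max(1e-3, s0 / 3); hi <- min(15, s0 * 3 + 0.5)
  opt <- optimize(f, c(lo, hi), tol = 1e-6)
  opt$minimum
}

em_run <- function(steps, init, max_iter, tol) {
  mu <- init$mu; sig <- init$sigma; sth <- init$sigma_theta
  A <- init$A; pi0 <- init$pi
  ok <- !is.na(steps$turn)
  th <- steps$turn[ok]
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  gammas <- NULL
  for (iter in seq_len(max_iter)) {
    logB <- emission_logdens(steps, mu, sig, sth)
    ll <- 0
    gam <- matrix(0, length(steps$speed), 2)
    xi <- matrix(0, 2, 2)
    pi_acc <- c(0, 0)
    for (j in seq_along(steps$lens)) {
      idx <- steps$starts[j]:(steps$starts[j] + steps$lens[j] - 1L)
      fb <- forward_backward(logB[idx, , drop = FALSE], A, pi0)
      ll <- ll + fb$loglik
      gam[idx, ] <- fb$gamma
      xi <- xi + fb$xi
      pi_acc <- pi_acc + fb$gamma[1, ]
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll) + 1)) {
      converged <- TRUE; gammas <- gam; break
    }
    ll_old <- ll
    gammas <- gam
    # M-step
    pi0 <- pi_acc / sum(pi_acc)
    rs <- rowSums(xi)
    if (all(rs > 0)) A <- xi / rs else A <- matrix(c(.5, .5, .5, .5), 2)
    A <- pmin(pmax(A, 1e-10), 1 - 1e-10)
    A <- A / rowSums(A)
    for (k in 1:2) {
      w <- gam[, k]
      Sw <- sum(w)
      if (Sw < 1e-6) next                   # empty state; caller restarts
      est <- tnorm_mle(Sw, sum(w * steps$speed), sum(w * steps$speed^2))
      mu[k] <- est["mu"]; sig[k] <- est["sigma"]
      if (sum(w[ok]) > 1e-6) sth[k] <- wrapnorm_mle(th, w[ok])
    }
  }
  list(mu = mu, sigma = sig, sigma_theta = sth, A = A, pi = pi0,
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       n_iterations = length(ll_trace), converged = converged,
       gamma = gammas)
}

median_split_init <- function(steps) {
  med <- stats::median(steps$speed)
  grp <- ifelse(steps$speed <= med, 1L, 2L)
  ok <- !is.na(steps$turn)
  mu <- sig <- sth <- numeric(2)
  for (k in 1:2) {
    s <- steps$speed[grp == k]
    mu[k] <- mean(s); sig[k] <- max(sd(s), 1e-3)
    a <- steps$turn[ok & grp == k]
    sth[k] <- if (length(a) >= 2) wrapnorm_sigma_moment(a) else 1
  }
  list(mu = mu, sigma = sig, sigma_theta = pmin(pmax(sth, 1e-2), 14),
       A = matrix(c(0.9, 0.1, 0.1, 0.9), 2), pi = c(0.5, 0.5))
}

jitter_init <- function(base) {
  list(mu = pmax(base$mu * exp(rnorm(2, 0, 0.3)), 1e-4),
       sigma = pmax(base$sigma * exp(rnorm(2, 0, 0.3)), 1e-3),
       sigma_theta = pmin(pmax(base$sigma_theta * exp(rnorm(2, 0, 0.3)), 1e-2), 14),
       A = { p <- runif(2, 0.02, 0.3)
             matrix(c(1 - p[1], p[2], p[1], 1 - p[2]), 2) },
       pi = c(0.5, 0.5))
}

finalize_fit <- function(res, steps, n_states) {
  if (n_states == 2 && res$mu[1] > res$mu[2]) {   # canonical order: slow first
    sw <- c(2L, 1L)
    res$mu <- res$mu[sw]; res$sigma <- res$sigma[sw]
    res$sigma_theta <- res$sigma_theta[sw]
    res$A <- res$A[sw, sw]; res$pi <- res$pi[sw]
    res$gamma <- res$gamma[, sw]
  }
  p12 <- res$A[1, 2]; p21 <- res$A[2, 1]
  alpha <- if (p12 + p21 > 1e-12) p21 / (p12 + p21) else res$pi[1]
  dwell <- if (p12 > 1e-12) (1 - alpha) / p12 else Inf
  params <- model_params(
    state_params(res$mu[1], res$sigma[1], res$sigma_theta[1]),
    state_params(res$mu[2], res$sigma[2], res$sigma_theta[2]),
    alpha = alpha, dwell = max(dwell, 1))
  post <- vector("list", length(steps$lens))
  for (j in seq_along(steps$lens)) {
    idx <- steps$starts[j]:(steps$starts[j] + steps$lens[j] - 1L)
    post[[j]] <- res$gamma[idx, , drop = FALSE]
  }
  structure(list(params = params, transition = res$A, initial = res$pi,
                 log_likelihood = res$loglik, ll_trace = res$ll_trace,
                 n_iterations = res$n_iterations, converged = res$converged,
                 state_posteriors = post, n_states = n_states),
            class = "prw_fit")
}

#' Fit the two-state model by EM
#'
#' Expectation--maximization over a two-state hidden Markov chain with
#' per-step emissions: speed from a zero-truncated Normal and turning
#' angle from a zero-mean wrapped Normal, independent given the state
#' (turning angles missing at the first step of a track, or where a
#' zero-length displacement leaves the angle undefined, contribute only
#' their speed). States are canonically ordered by ascending mean speed,
#' so state 1 is the slower state.
#'
#' @param tracks A list of [cell_track()] objects (or a single track).
#' @param init `"median-split"` (split steps at the median speed) for
#'   the first start; further starts jitter it.
#' @param n_restarts Total number of EM starts (default 5); the best
#'   final log-likelihood wins.
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param tol Relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param seed RNG seed for the jittered restarts.
#' @return Object of class `prw_fit`: `params` ([model_params()]),
#'   `transition`, `log_likelihood`, `ll_trace`, `n_iterations`,
#'   `converged` and per-track `state_posteriors`.
#' @export
fit_two_state <- function(tracks, init = "median-split", n_restarts = 5,
                          max_iter = 500, tol = 1e-6, seed = 1) {
  steps <- prep_steps(tracks)
  if (any(steps$lens < 10))
    warning("tracks with fewer than 10 steps give weak state estimates")
  base <- median_split_init(steps)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ini <- if (r == 1) base else with_seed(seed + r, jitter_init(base))
    res <- em_run(steps, ini, max_iter, tol)
    if (min(colSums(res$gamma)) < 1e-3) next   # collapsed state, drop start
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) stop("all EM starts collapsed a state", call. = FALSE)
  finalize_fit(best, steps, 2L)
}

#' Fit the one-state (single-mode) model
#'
#' Maximum likelihood for a single migration state: the truncated-Normal
#' speed MLE is found numerically and the wrapped-Normal orientation SD
#' is estimated from circular moments (with a 1-D likelihood
#' refinement). Used as the baseline the two-state model is compared
#' against.
#'
#' @inheritParams fit_two_state
#' @return Object of class `prw_fit` with `n_states = 1`.
#' @export
fit_one_state <- function(tracks) {
  steps <- prep_steps(tracks)
  n <- length(steps$speed)
  est <- tnorm_mle(n, sum(steps$speed), sum(steps$speed^2))
  ok <- !is.na(steps$turn)
  sth <- wrapnorm_mle(steps$turn[ok], rep(1, sum(ok)))
  ll <- sum(dtnorm0(steps$speed, est["mu"], est["sigma"], log = TRUE)) +
        sum(dwrapnorm(steps$turn[ok], sth, log = TRUE))
  sp <- state_params(est[["mu"]], est[["sigma"]], sth)
  post <- lapply(steps$lens, function(L) matrix(1, L, 1))
  structure(list(params = model_params(sp, sp, alpha = 1),
                 transition = diag(2), initial = c(1, 0),
                 log_likelihood = ll, ll_trace = ll, n_iterations = 1L,
                 converged = TRUE, state_posteriors = post, n_states = 1L),
            class = "prw_fit")
}

#' Decode hidden migration states of a track
#'
#' Viterbi most-probable state path and forward-backward posteriors
#' under fitted (or known) model parameters.
#'
#' @param track A [cell_track()].
#' @param fit A `prw_fit` object or a [model_params()] object (the
#'   transition matrix is then derived from alpha and dwell, with the
#'   stationary initial distribution).
#' @return List with `path` (integer states), `posteriors` (T x 2
#'   matrix), `time_in_state1` (fraction of Viterbi steps in state 1)
#'   and `loglik`.
#' @export
decode_states <- function(track, fit) {
  if (inherits(fit, "model_params")) {
    A <- transition_matrix(fit)
    pi0 <- c(fit$alpha, 1 - fit$alpha)
    pars <- fit
  } else if (inherits(fit, "prw_fit")) {
    A <- fit$transition
    pi0 <- fit$initial
    pars <- fit$params
  } else stop("'fit' must be a prw_fit or model_params object", call. = FALSE)
  steps <- prep_steps(track)
  mu <- c(pars$state1$mu_s, pars$state2$mu_s)
  sig <- pmax(c(pars$state1$sigma_s, pars$state2$sigma_s), 1e-6)
  sth <- pmax(c(pars$state1$sigma_theta, pars$state2$sigma_theta), 1e-3)
  logB <- emission_logdens(steps, mu, sig, sth)
  Tn <- nrow(logB)
  lpi <- log(pi0); lA <- log(A)   # exact zeros stay impossible (-Inf)
  # Viterbi
  delta <- matrix(-Inf, Tn, 2); psi <- matrix(0L, Tn, 2)
  delta[1, ] <- lpi + logB[1, ]
  if (Tn > 1) for (t in 2:Tn) for (k in 1:2) {
    v <- delta[t - 1, ] + lA[, k]
    psi[t, k] <- which.max(v)
    delta[t, k] <- max(v) + logB[t, k]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  fb <- forward_backward(logB, A, pi0)
  list(path = path, posteriors = fb$gamma,
       time_in_state1 = mean(path == 1L), loglik = fb$loglik)
}

#' Per-state summary of a fitted track set
#'
#' Posterior-weighted empirical statistics in the style of a two-state
#' migration table: per-state mean speed, directional variance over a
#' time lag, and the occupancy of state 1 (alpha).
#'
#' @param tracks List of [cell_track()] objects.
#' @param fit A `prw_fit` or [model_params()] object.
#' @param lag Time lag (minutes) for the directional variance; default
#'   twice the frame interval (e.g. an 8-min window for 4-min frames).
#' @return List with `by_state` (data frame: state, mean_speed,
#'   directional_variance, occupancy) and `alpha` (posterior mean
#'   fraction of time in state 1).
#' @export
summarize_states <- function(tracks, fit, lag = NULL) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  if (is.null(lag)) lag <- 2 * tracks[[1]]$dt
  dec <- lapply(tracks, decode_states, fit = fit)
  gam <- do.call(rbind, lapply(dec, `[[`, "posteriors"))
  st <- do.call(rbind, lapply(tracks, function(tr) {
    s <- step_stats(tr)
    k <- as.integer(round(lag / tr$dt))
    n <- nrow(s)
    dh <- rep(NA_real_, n)
    if (n > k) dh[(1 + k):n] <- s$heading[(1 + k):n] - s$heading[1:(n - k)]
    cbind(speed = s$speed, dh = dh)
  }))
  by_state <- do.call(rbind, lapply(1:2, function(k) {
    w <- gam[, k]
    ok <- !is.na(st[, "dh"])
    dv <- if (sum(w[ok]) > 0) {
      cw <- sum(w[ok] * cos(st[ok, "dh"])) / sum(w[ok])
      sw <- sum(w[ok] * sin(st[ok, "dh"])) / sum(w[ok])
      1 - sqrt(cw^2 + sw^2)
    } else NA_real_
    data.frame(state = k,
               mean_speed = sum(w * st[, "speed"]) / sum(w),
               directional_variance = dv,
               occupancy = mean(w))
  }))
  list(by_state = by_state, alpha = mean(gam[, 1]))
}
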