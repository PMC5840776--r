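two_state <- model_params(state_params(0.1, 0.05, 2.0),
                          state_params(1.0, 0.2, 0.3),
                          alpha = 0.5, dwell = 20)

test_that("simulation honours deterministic limits and the seed contract", {
  det <- model_params(state_params(1, 0, 0), state_params(1, 0, 0),
                      alpha = 1, dwell = 10)
  sim <- simulate_tracks(det, 1, 10, dt = 1, seed = 3)
  p <- sim$tracks[[1]]$positions
  expect_equal(sqrt(sum(p[11, ]^2)), 10)                  # straight line
  expect_equal(max(abs(step_stats(sim$tracks[[1]])$turn), na.rm = TRUE), 0)
  all1 <- simulate_tracks(model_params(state_params(0.5, 0.1, 1),
                                       state_params(2, 0.1, 1),
                                       alpha = 1, dwell = 5),
                          5, 50, dt = 2, seed = 1)
  expect_true(all(unlist(all1$states) == 1L))
  expect_identical(simulate_tracks(two_state, 3, 20, 4, seed = 8),
                   simulate_tracks(two_state, 3, 20, 4, seed = 8))
})

test_that("memoryless-orientation walks obey the uncorrelated R^2 law", {
  # sigma_theta >= 2*pi: headings effectively independent, so
  # E[R^2(n)] = n E[(s dt)^2]; Monte-Carlo oracle over 1e4 cells, 3-sigma
  mu <- 1; sig <- 0.1; dtm <- 1; nst <- 20
  un <- model_params(state_params(mu, sig, 2 * pi), state_params(mu, sig, 2 * pi),
                     alpha = 0.5, dwell = 5)
  sim <- simulate_tracks(un, 1e4, nst, dt = dtm, seed = 13)
  r2 <- vapply(sim$tracks, function(tr)
    sum((tr$positions[nst + 1, ] - tr$positions[1, ])^2), numeric(1))
  expected <- nst * (mu^2 + sig^2) * dtm^2   # truncation negligible here
  expect_lt(abs(mean(r2) - expected), 3 * sd(r2) / sqrt(length(r2)))
})

test_that("step statistics report speeds and wrapped turning angles", {
  tr <- cell_track(cbind(c(0, 1, 2, 3), c(0, 0, 0, 0)), dt = 2)
  s <- step_stats(tr)
  expect_equal(s$speed, rep(0.5, 3))
  expect_equal(s$turn[-1], c(0, 0))
  sq <- cell_track(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), dt = 1)
  expect_equal(abs(step_stats(sq)$turn[-1]), rep(pi / 2, 2))
  # zero-length displacement flags the undefined turning angle
  z <- cell_track(cbind(c(0, 1, 1, 2), c(0, 0, 0, 0)), dt = 1)
  expect_equal(step_stats(z)$turn_ok, c(FALSE, FALSE, FALSE))
  # empirical mean speed matches the truncation-corrected mean
  slow <- model_params(state_params(0.1, 0.2, 1), state_params(0.1, 0.2, 1),
                       alpha = 0.5, dwell = 5)
  sim <- simulate_tracks(slow, 100, 100, dt = 1, seed = 5)
  sp <- unlist(lapply(sim$tracks, function(tr) step_stats(tr)$speed))
  expect_lt(abs(mean(sp) - rhoscreen:::tnorm0_mean(0.1, 0.2)),
            3 * sd(sp) / sqrt(length(sp)))
})

test_that("directional variance spans persistent to uncorrelated motion", {
  line <- cell_track(cbind(0:20, 0:20), dt = 4)
  expect_equal(directional_variance(line, lag = 8), 0)
  # i.i.d. uniform directions -> 1 at large n
  set.seed(7)
  steps <- cbind(cos(runif(1e4, -pi, pi)), sin(runif(1e4, -pi, pi)))
  rw <- cell_track(rbind(c(0, 0), apply(steps, 2, cumsum)), dt = 4)
  expect_lt(abs(directional_variance(rw, lag = 4) - 1), 0.03)
  expect_error(directional_variance(line, lag = 3), "multiple")
  expect_error(directional_variance(cell_track(cbind(0:2, 0:2), dt = 4), 8),
               "usable")
})

test_that("marginal dx density integrates to one and matches closed forms", {
  dx <- marginal_dx_density(two_state, dt = 4)
  I <- integrate(dx$pdf, -dx$xmax, 0, rel.tol = 1e-9)$value +
       integrate(dx$pdf, 0, dx$xmax, rel.tol = 1e-9)$value
  expect_lt(abs(I - 1), 1e-6)
  # sigma_s -> 0 reduces to the arcsine law on (-mu dt, mu dt)
  da <- marginal_dx_density(state_params(1, 0, 0.3), dt = 2)
  xs <- seq(-1.9, 1.9, by = 0.1)
  expect_equal(da$pdf(xs), 1 / (pi * sqrt((1 * 2)^2 - xs^2)), tolerance = 1e-10)
  expect_equal(da$cdf(0), 0.5)
  expect_equal(da$cdf(2), 1)
})

test_that("dx density matches a simulated step histogram", {
  mix <- model_params(state_params(0.2, 0.1, 2.0), state_params(1.0, 0.3, 0.8),
                      alpha = 0.4, dwell = 5)
  sim <- simulate_tracks(mix, 200, 100, dt = 4, seed = 11)
  dxs <- unlist(lapply(sim$tracks, function(tr) step_stats(tr)$dx))
  dx <- marginal_dx_density(mix, dt = 4)
  expect_lt(ks_statistic(dxs, dx$cdf), 0.03)
})

test_that("forward likelihood equals brute-force path enumeration", {
  sim <- simulate_tracks(two_state, 3, 6, dt = 4, seed = 17)
  for (tr in sim$tracks) {
    ll_forward <- decode_states(tr, two_state)$loglik
    ll_brute <- oracle_brute_force_loglik(tr, two_state)
    expect_equal(ll_forward, ll_brute, tolerance = 1e-10)
  }
})

test_that("EM fits recover generating parameters", {
  sim <- simulate_tracks(two_state, 60, 120, dt = 4, seed = 7)
  fit <- fit_two_state(sim$tracks, n_restarts = 3, seed = 42)
  expect_true(all(diff(fit$ll_trace) >= -1e-6))      # EM monotonicity
  expect_lte(fit$params$state1$mu_s, fit$params$state2$mu_s)  # canonical order
  expect_lt(rel_err(fit$params$state1$mu_s, 0.1), 0.15)
  expect_lt(rel_err(fit$params$state2$mu_s, 1.0), 0.15)
  expect_lt(abs(fit$params$alpha - 0.5), 0.1)
  # posteriors are proper probabilities
  post <- fit$state_posteriors[[1]]
  expect_true(all(post >= 0 & post <= 1))
  expect_equal(rowSums(post), rep(1, nrow(post)))
})

test_that("one-state fits are exact enough and expose model inadequacy", {
  one <- model_params(state_params(0.5, 0.15, 0.8), state_params(0.5, 0.15, 0.8),
                      alpha = 1, dwell = 5)
  sim <- simulate_tracks(one, 100, 100, dt = 2, seed = 19)   # 1e4 steps
  f1 <- fit_one_state(sim$tracks)
  expect_lt(rel_err(f1$params$state1$mu_s, 0.5), 0.05)
  expect_lt(rel_err(f1$params$state1$sigma_s, 0.15), 0.05)
  expect_lt(rel_err(f1$params$state1$sigma_theta, 0.8), 0.05)
  # two-state data: the two-state fit wins beyond the AIC penalty
  sim2 <- simulate_tracks(two_state, 40, 100, dt = 4, seed = 23)
  f1b <- fit_one_state(sim2$tracks)
  f2b <- fit_two_state(sim2$tracks, n_restarts = 2, seed = 1)
  expect_gt(f2b$log_likelihood - f1b$log_likelihood, 6)  # 6 extra parameters
  # one-state data fitted with two states: little gain or degenerate alpha
  f2a <- fit_two_state(sim$tracks, n_restarts = 2, seed = 1)
  gain <- f2a$log_likelihood - f1$log_likelihood
  expect_gt(gain, -1)   # EM stops on a relative tolerance; ~0 on 1e4 nats
  expect_true(gain < 20 || min(f2a$params$alpha, 1 - f2a$params$alpha) < 0.05)
  expect_error(fit_one_state(list(cell_track(matrix(0, 5, 2), 1))), "degenerate")
})

test_that("fitted dx density explains the data at least as well as one state", {
  sim <- simulate_tracks(two_state, 60, 120, dt = 4, seed = 29)
  dxs <- unlist(lapply(sim$tracks, function(tr) step_stats(tr)$dx))
  f1 <- fit_one_state(sim$tracks)
  f2 <- fit_two_state(sim$tracks, n_restarts = 2, seed = 2)
  ks1 <- ks_statistic(dxs, marginal_dx_density(f1$params, dt = 4)$cdf)
  ks2 <- ks_statistic(dxs, marginal_dx_density(f2$params, dt = 4)$cdf)
  expect_lte(ks2, ks1)
})

test_that("state decoding matches truth and degenerate occupancy", {
  sim <- simulate_tracks(two_state, 20, 120, dt = 4, seed = 31)
  fit <- fit_two_state(sim$tracks, n_restarts = 2, seed = 3)
  acc <- mean(unlist(lapply(seq_along(sim$tracks), function(i)
    decode_states(sim$tracks[[i]], fit)$path == sim$states[[i]])))
  expect_gte(acc, 0.9)
  # alpha = 1 parameters decode everything as state 1
  a1 <- model_params(state_params(0.2, 0.1, 1), state_params(1, 0.2, 0.3),
                     alpha = 1, dwell = 5)
  dec <- decode_states(sim$tracks[[1]], a1)
  expect_true(all(dec$path == 1L))
})

test_that("state summaries report ordered truncation-corrected speeds", {
  sim <- simulate_tracks(two_state, 60, 120, dt = 4, seed = 37)
  fit <- fit_two_state(sim$tracks, n_restarts = 2, seed = 4)
  sm <- summarize_states(sim$tracks, fit)
  expect_lte(sm$by_state$mean_speed[1], sm$by_state$mean_speed[2])
  m1 <- rhoscreen:::tnorm0_mean(0.1, 0.05)
  m2 <- rhoscreen:::tnorm0_mean(1.0, 0.2)
  expect_lt(rel_err(sm$by_state$mean_speed[1], m1), 0.15)
  expect_lt(rel_err(sm$by_state$mean_speed[2], m2), 0.15)
  expect_lt(abs(sm$alpha - 0.5), 0.1)
  # slow state is less persistent over the 8-min window
  expect_gt(sm$by_state$directional_variance[1],
            sm$by_state$directional_variance[2])
})

test_that("fits are invariant to a global rotation of all tracks", {
  sim <- simulate_tracks(two_state, 30, 80, dt = 4, seed = 41)
  f <- fit_two_state(sim$tracks, n_restarts = 1)
  fr <- fit_two_state(rotate_tracks(sim$tracks, 0.7), n_restarts = 1)
  expect_equal(f$params$state1$mu_s, fr$params$state1$mu_s, tolerance = 1e-4)
  expect_equal(f$params$state2$sigma_theta, fr$params$state2$sigma_theta,
               tolerance = 1e-4)
  expect_equal(f$params$alpha, fr$params$alpha, tolerance = 1e-3)
  expect_equal(f$log_likelihood, fr$log_likelihood, tolerance = 1e-6)
})
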