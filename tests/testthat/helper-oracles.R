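# Independent oracles used by several test files. These deliberately
# re-derive densities and likelihoods from first principles rather than
# calling the package's internals.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# zero-truncated Normal density, written independently of the package
oracle_dtnorm0 <- function(x, mu, sigma) {
  ifelse(x < 0, 0, dnorm(x, mu, sigma) / pnorm(mu / sigma))
}

# wrapped-Normal(0, sigma^2) density by direct series summation
oracle_dwrapnorm <- function(theta, sigma, K = 30) {
  out <- 0
  for (k in -K:K) out <- out + dnorm(theta + 2 * pi * k, 0, sigma)
  out
}

# per-step emission probabilities for a track under given model params
oracle_emissions <- function(track, params) {
  s <- step_stats(track)
  sp <- list(params$state1, params$state2)
  B <- sapply(sp, function(p) {
    b <- oracle_dtnorm0(s$speed, p$mu_s, p$sigma_s)
    ok <- !is.na(s$turn)
    b[ok] <- b[ok] * oracle_dwrapnorm(s$turn[ok], p$sigma_theta)
    b
  })
  matrix(B, ncol = 2)
}

# total track likelihood by explicit enumeration of all 2^T state paths
oracle_brute_force_loglik <- function(track, params) {
  B <- oracle_emissions(track, params)
  A <- transition_matrix(params)
  pi0 <- c(params$alpha, 1 - params$alpha)
  Tn <- nrow(B)
  total <- 0
  for (code in 0:(2^Tn - 1)) {
    path <- as.integer(intToBits(code))[1:Tn] + 1L
    p <- pi0[path[1]] * B[1, path[1]]
    if (Tn > 1) for (t in 2:Tn) p <- p * A[path[t - 1], path[t]] * B[t, path[t]]
    total <- total + p
  }
  log(total)
}

# rotate every track of a list by a fixed angle about the origin
rotate_tracks <- function(tracks, phi) {
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  lapply(tracks, function(tr) cell_track(tr$positions %*% t(R), tr$dt))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
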