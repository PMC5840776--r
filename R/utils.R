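# Internal helpers shared across modules.

#' @importFrom stats dnorm pnorm qnorm rnorm runif sd integrate optim optimize
#'   approx setNames aggregate complete.cases weighted.mean
NULL

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

as_binary_matrix <- function(x, name = "mask") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stop(sprintf("'%s' must be a 2-D matrix", name), call. = FALSE)
  mode(x) <- "numeric"
  x > 0.5
}

as_intensity_matrix <- function(x, name = "image") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric 2-D matrix", name), call. = FALSE)
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  if (any(x < 0)) stop(sprintf("'%s' must be nonnegative", name), call. = FALSE)
  x
}

# 8-connected component labelling by breadth-first flood fill.
# EBImage::bwlabel is 4-connected; wound detection specifies 8-connectivity
# so diagonal pixel chains do not split a region.
label_components8 <- function(mask) {
  mask <- as_binary_matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(mask)
  queue <- integer(length(idx_all))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dc in -1:1) {
        c2 <- cc + dc
        if (c2 < 1L || c2 > nc) next
        base <- (c2 - 1L) * nr
        for (dr in -1:1) {
          r2 <- r + dr
          if (r2 < 1L || r2 > nr) next
          q <- base + r2
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            tail <- tail + 1L
            queue[tail] <- q
          }
        }
      }
    }
  }
  lab
}

# Pixel-centre rasterization of an axis-aligned ellipse (disc when a == b).
rasterize_ellipse <- function(dim, cx, cy, a, b) {
  x <- matrix(seq_len(dim[1]), dim[1], dim[2])
  y <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Density of a Normal(mu, sigma^2) truncated to [0, Inf).
dtnorm0 <- function(x, mu, sigma, log = FALSE) {
  z <- pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  out <- dnorm(x, mu, sigma, log = TRUE) - z
  out[x < 0] <- -Inf
  if (log) out else exp(out)
}

# Mean of the zero-truncated Normal: mu + sigma * hazard(-mu/sigma).
tnorm0_mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

rtnorm0 <- function(n, mu, sigma) {
  # inverse-CDF sampling; exact for the zero-truncated Normal
  p0 <- pnorm(0, mu, sigma)
  qnorm(p0 + runif(n) * (1 - p0), mu, sigma)
}

# Wrapped-Normal(0, sigma^2) density on (-pi, pi].
dwrapnorm <- function(theta, sigma, log = FALSE) {
  sigma <- max(sigma, 1e-8)
  if (sigma > 10) {
    out <- rep(1 / (2 * pi), length(theta))
    return(if (log) log(out) else out)
  }
  K <- min(50L, as.integer(ceiling((6 * sigma + pi) / (2 * pi))) + 1L)
  ks <- (-K):K
  dens <- rowSums(vapply(ks, function(k) dnorm(theta + 2 * pi * k, 0, sigma),
                         numeric(length(theta))))
  if (log) log(dens) else dens
}

wrap_angle <- function(theta) {
  # wrap to (-pi, pi]
  w <- ((theta + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# Weighted circular-moment estimate of the wrapped-Normal SD.
wrapnorm_sigma_moment <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  rbar <- sqrt(sum(w * cos(theta))^2 + sum(w * sin(theta))^2) / sum(w)
  rbar <- min(max(rbar, 1e-12), 1 - 1e-12)
  sqrt(-2 * log(rbar))
}
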