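# Independent oracles and small fixture builders used across the suite.

# Brute-force multilinear interpolation by successive 1D linear interpolation
# along each axis (structurally unlike the package's corner-weight sum).
oracle_interp <- function(axes, comps, p) {
  vapply(comps, function(a) {
    cur <- a
    for (j in seq_along(axes)) {
      # interpolate along the first remaining axis at p[j]
      d <- dim(cur) %||% length(cur)
      if (length(d) == 1L) {
        cur <- stats::approx(axes[[j]], cur, xout = p[j], rule = 2)$y
      } else {
        flat <- matrix(cur, nrow = d[1])
        cur <- array(apply(flat, 2, function(col)
          stats::approx(axes[[j]], col, xout = p[j], rule = 2)$y),
          dim = d[-1])
      }
    }
    as.numeric(cur)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force central-moment statistics by explicit summation loops.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  list(mean = mu, m2 = m2,
       skewness = if (m2 > 0) m3 / m2^1.5 else 0,
       kurtosis = if (m2 > 0) m4 / m2^2 else 0)
}

# Inverse-Gaussian CDF (first-passage law of Brownian motion with drift),
# numerically stable for large shape via log-scale second term.
pinvgauss <- function(q, mean, shape) {
  vapply(q, function(x) {
    if (x <= 0) return(0)
    a <- sqrt(shape / x)
    t1 <- stats::pnorm(a * (x / mean - 1))
    t2 <- exp(2 * shape / mean +
                stats::pnorm(-a * (x / mean + 1), log.p = TRUE))
    min(1, t1 + t2)
  }, numeric(1))
}

# Uniform 3D field with constant velocity vel over box [0, ext] per axis.
uniform_field <- function(vel = c(10, 0, 0), ext = c(250, 80, 80), n = 3L) {
  axes <- lapply(ext, function(e) seq(0, e, length.out = n))
  shape <- rep(n, 3)
  comps <- lapply(vel, function(v) array(v, dim = shape))
  grid_velocity_field(axes, comps)
}

# Field sampled from an affine function per component; returns field plus the
# affine evaluators.
affine_field <- function(axes, coef) {
  grids <- expand.grid(axes)
  comps <- lapply(coef, function(cf) {
    vals <- cf[1] + as.matrix(grids) %*% cf[-1]
    array(vals, dim = lengths(axes))
  })
  list(field = grid_velocity_field(axes, comps),
       f = lapply(coef, function(cf) function(p) cf[1] + sum(cf[-1] * p)))
}

random_axes <- function(ndim, max_n = 5L) {
  lapply(seq_len(ndim), function(j)
    cumsum(c(stats::runif(1, -5, 5),
             stats::runif(sample(1:(max_n - 1), 1) + 0L, 0.2, 3))))
}
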