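# Shared builders and numeric helpers for the test suite.

two_particle_system <- function() make_gaussian_network(2)

two_particle_mapping <- function() cg_mapping(matrix(c(1, 0), 1))

# Central finite-difference check of fine_forces against fine_energy.
fd_force_error <- function(system, r, h = 1e-6) {
  r <- matrix(r, system$n_particles, system$dim)
  f <- fine_forces(system, r)
  fd <- r
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    rp <- r; rm <- r
    rp[i, j] <- rp[i, j] + h
    rm[i, j] <- rm[i, j] - h
    fd[i, j] <- -(fine_energy(system, rp) - fine_energy(system, rm)) / (2 * h)
  }
  max(abs(f - fd)) / max(1, max(abs(f)))
}

# Pooled regression slope of y on x through the origin, with its standard
# error (the targets' conditional mean is linear in R through the origin).
origin_slope <- function(x, y) {
  sxx <- sum(x^2)
  b <- sum(x * y) / sxx
  resid <- y - b * x
  se <- sqrt(sum(resid^2) / (length(x) - 1) / sxx)
  list(slope = b, se = se)
}

# Batch-means standard error of the mean of a correlated series.
batch_means_se <- function(x, n_blocks = 30) {
  bs <- floor(length(x) / n_blocks)
  bm <- vapply(seq_len(n_blocks),
               function(b) mean(x[(b - 1) * bs + seq_len(bs)]), 0)
  sd(bm) / sqrt(n_blocks)
}

# Quadratic-basis parameters -> implied precision matrix of 0.5 v' P v.
quadratic_params_to_precision <- function(theta, spec) {
  D <- spec$n_sites * spec$dim
  P <- matrix(0, D, D)
  for (f in seq_len(nrow(spec$idx))) {
    a <- spec$idx[f, 1]; b <- spec$idx[f, 2]
    if (a == b) P[a, a] <- 2 * theta[f]
    else { P[a, b] <- theta[f]; P[b, a] <- theta[f] }
  }
  P
}

# Tilted 6 kT double well in one coordinate:
# u(x) = 6 (x^2 - 1)^2 + 0.5 x (up to a constant).
tilted_double_well_potential <- function() {
  te <- trainable_energy("linear", feature_poly_projection(w = 1,
                                                           powers = c(1, 2, 4)),
                         params = c(0.5, -12, 6))
  cg_potential(trainable = te)
}

tilted_double_well_reference <- function(grid = seq(-2.5, 2.5,
                                                    length.out = 801)) {
  pot <- tilted_double_well_potential()
  u <- vapply(grid, function(x) cg_energy(pot, matrix(x)), 0)
  pmf_oracle(grid, u)
}

# Two mixed AR(1) (discrete OU) series with prescribed lag-autocorrelations.
ou_mixture <- function(n, lag, auto_slow = 0.9, auto_fast = 0.1,
                       mix = matrix(c(1, 0.6, -0.4, 1.2), 2, 2), seed = 1) {
  set.seed(seed)
  rs <- auto_slow^(1 / lag); rf <- auto_fast^(1 / lag)
  zs <- rnorm(n); zf <- rnorm(n)
  xs <- stats::filter(sqrt(1 - rs^2) * zs, rs, method = "recursive")
  xf <- stats::filter(sqrt(1 - rf^2) * zf, rf, method = "recursive")
  list(series = cbind(xs, xf) %*% t(mix), slow = as.numeric(xs), mix = mix)
}
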