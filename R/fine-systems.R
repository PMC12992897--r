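# Synthetic fine-grained reference systems.
#
# All energies are dimensionless (thermal units, k_B T = 1). Systems carry
# analytic potentials u(r) and forces f(r) = -grad u(r), so every generated
# dataset has exact force labels and an independently computable potential of
# mean force along the coarse coordinate.

.fine_kinds <- c("gaussian_network", "double_well_chain", "uniform_box")

.new_fine_system <- function(kind, n_particles, dim, params) {
  stopifnot(kind %in% .fine_kinds, n_particles >= 1, dim %in% 1:3)
  structure(list(kind = kind, n_particles = as.integer(n_particles),
                 dim = as.integer(dim), params = params),
            class = "fine_system")
}

#' @export
print.fine_system <- function(x, ...) {
  cat(sprintf("<fine_system: %s, %d particles, dim %d>\n",
              x$kind, x$n_particles, x$dim))
  invisible(x)
}

#' Gaussian network fine-grained system
#'
#' Builds a harmonic network with quadratic energy `u(r) = 1/2 r' K r` per
#' spatial dimension, the exactly solvable oracle system: its samples,
#' marginals and mean forces all have closed forms.
#'
#' @param n_particles Number of particles (>= 2).
#' @param dim Spatial dimension (1, 2 or 3).
#' @param coupling_spec Either a symmetric positive-definite precision matrix
#'   `K` (field `K`), or a list with `spring` (nearest-neighbour chain spring
#'   constant) and `tether` (diagonal tether), giving
#'   `K = spring * L_chain + tether * I`.
#' @return A `fine_system` of kind `gaussian_network` with `K` in `params`.
#' @export
#' @examples
#' sys <- make_gaussian_network(2, coupling_spec = list(spring = 1, tether = 1))
#' sys$params$K  # [[2,-1],[-1,2]]
make_gaussian_network <- function(n_particles, dim = 1,
                                  coupling_spec = list(spring = 1, tether = 1)) {
  stopifnot(n_particles >= 2)
  if (!is.null(coupling_spec$K)) {
    K <- as.matrix(coupling_spec$K)
  } else {
    n <- n_particles
    L <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      L[i, i] <- L[i, i] + 1; L[i + 1, i + 1] <- L[i + 1, i + 1] + 1
      L[i, i + 1] <- L[i, i + 1] - 1; L[i + 1, i] <- L[i + 1, i] - 1
    }
    K <- coupling_spec$spring * L + coupling_spec$tether * diag(n)
  }
  if (nrow(K) != n_particles || !isSymmetric(unname(K), tol = 1e-10))
    stop("coupling_spec must yield a symmetric n_particles x n_particles matrix")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("precision matrix is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)))
  .new_fine_system("gaussian_network", n_particles, dim, list(K = unname(K)))
}

#' Double-well chain fine-grained system
#'
#' A one-dimensional two-state toy: two end particles bonded by a double well
#' `u_dw(d) = a (d^2 - d0^2)^2` in the signed bond displacement `d = x2 - x1`,
#' plus `n_bath` bath particles tied to the bond midpoint through
#' `1/2 k_bath (y_i - c_couple d^2)^2` with `y_i` the offset from the
#' midpoint. The bath integrates out exactly (its Gaussian integral does not
#' depend on `d`), so the PMF over `d` is the bare double well; at the same
#' time the bond-length-dependent rest offset makes the instantaneous mapped
#' forces fluctuate in a way no constant linear force map can cancel, giving
#' the system irreducible coarse-grained force noise.
#'
#' @param n_bath Number of bath particles (>= 0).
#' @param params List with `a` (> 0, barrier scale; barrier height is
#'   `a d0^4` k_BT), `d0` (> 0, well position), `k_bath` (bath stiffness) and
#'   `c_couple` (bond-length coupling of the bath rest offset).
#' @return A `fine_system` of kind `double_well_chain` (dim 1,
#'   `2 + n_bath` particles; particles 1 and 2 are the bond).
#' @export
make_double_well_chain <- function(n_bath = 4,
                                   params = list(a = 6, d0 = 1,
                                                 k_bath = 100, c_couple = 0.5)) {
  p <- modifyList(list(a = 6, d0 = 1, k_bath = 100, c_couple = 0.5), params)
  if (p$a <= 0) stop("double-well parameter a must be > 0")
  if (p$d0 <= 0) stop("double-well parameter d0 must be > 0")
  if (p$k_bath < 0) stop("k_bath must be >= 0")
  p$n_bath <- as.integer(n_bath)
  .new_fine_system("double_well_chain", 2L + as.integer(n_bath), 1L, p)
}

#' Uniform (zero-potential) box system
#'
#' A flat potential on a bounded box, used as a degenerate reference: its PMF
#' along any coordinate is identically zero.
#'
#' @param n_particles,dim System size.
#' @param half_width Half-width of the box support per coordinate.
#' @return A `fine_system` of kind `uniform_box`.
#' @export
make_uniform_box <- function(n_particles = 1, dim = 1, half_width = 1) {
  .new_fine_system("uniform_box", n_particles, dim,
                   list(half_width = half_width))
}

#' Potential energy of a fine-grained system
#'
#' @param system A `fine_system`.
#' @param r Configuration matrix `[n_particles, dim]`.
#' @return Scalar energy in thermal units.
#' @export
fine_energy <- function(system, r) {
  r <- matrix(r, nrow = system$n_particles, ncol = system$dim)
  switch(system$kind,
    gaussian_network = {
      K <- system$params$K
      0.5 * sum(vapply(seq_len(system$dim),
                       function(j) c(crossprod(r[, j], K %*% r[, j])), 0))
    },
    double_well_chain = {
      p <- system$params
      x <- r[, 1]
      d <- x[2] - x[1]
      m <- (x[1] + x[2]) / 2
      u <- p$a * (d^2 - p$d0^2)^2
      if (p$n_bath > 0) {
        s <- (x[-(1:2)] - m) - p$c_couple * d^2
        u <- u + 0.5 * p$k_bath * sum(s^2)
      }
      u
    },
    uniform_box = 0
  )
}

#' Forces of a fine-grained system
#'
#' Analytic negative gradient of [fine_energy()].
#'
#' @inheritParams fine_energy
#' @return Force matrix `[n_particles, dim]` in thermal units.
#' @export
fine_forces <- function(system, r) {
  r <- matrix(r, nrow = system$n_particles, ncol = system$dim)
  switch(system$kind,
    gaussian_network = -system$params$K %*% r,
    double_well_chain = {
      p <- system$params
      x <- r[, 1]
      d <- x[2] - x[1]
      g <- numeric(length(x))
      dudd <- 4 * p$a * d * (d^2 - p$d0^2)
      g[1] <- -dudd
      g[2] <- dudd
      if (p$n_bath > 0) {
        m <- (x[1] + x[2]) / 2
        s <- (x[-(1:2)] - m) - p$c_couple * d^2
        ks <- p$k_bath * s
        gp <- 2 * p$c_couple * d          # d(offset)/dd
        g[1] <- g[1] + sum(ks) * (-0.5 + gp)
        g[2] <- g[2] + sum(ks) * (-0.5 - gp)
        g[-(1:2)] <- ks
      }
      matrix(-g, ncol = 1)
    },
    uniform_box = matrix(0, system$n_particles, system$dim)
  )
}

#' Fine-grained dataset of configurations and force labels
#'
#' @param positions Array `[n_frames, n_particles, dim]`.
#' @param forces Array of the same shape.
#' @param weights Optional non-negative per-frame weights.
#' @param metadata List of generator provenance (system kind, seed, sampler,
#'   bias description).
#' @return A `fine_dataset`.
#' @export
fine_dataset <- function(positions, forces, weights = NULL, metadata = list()) {
  stopifnot(length(dim(positions)) == 3L,
            identical(dim(positions), dim(forces)))
  if (!is.null(weights)) {
    stopifnot(length(weights) == dim(positions)[1], all(weights >= 0))
    if (sum(weights) <= 0) stop("weights must not all be zero")
  }
  structure(list(positions = positions, forces = forces, weights = weights,
                 metadata = metadata),
            class = "fine_dataset")
}

#' @export
print.fine_dataset <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<fine_dataset: %d frames, %d particles, dim %d>\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Exact i.i.d. samples from a Gaussian network
#'
#' Draws frames from the Boltzmann density `exp(-u)` of a
#' [make_gaussian_network()] system using a Cholesky factor of `K`, with the
#' analytic forces recorded per frame.
#'
#' @param system A `gaussian_network` system.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; runs are bit-reproducible.
#' @return A [fine_dataset()].
#' @export
sample_gaussian_exact <- function(system, n_frames, seed = 1) {
  if (system$kind != "gaussian_network")
    stop("sample_gaussian_exact requires a gaussian_network system")
  if (n_frames < 1) stop("n_frames must be >= 1")
  K <- system$params$K
  U <- chol(K)                     # K = U'U, so solve(U, z) ~ N(0, K^-1)
  n <- system$n_particles; d <- system$dim
  .maybe_seed(seed)
  pos <- array(0, dim = c(n_frames, n, d))
  for (j in seq_len(d)) {
    Z <- matrix(rnorm(n_frames * n), nrow = n)
    pos[, , j] <- t(backsolve(U, Z))
  }
  frc <- array(0, dim = c(n_frames, n, d))
  for (j in seq_len(d)) frc[, , j] <- -pos[, , j] %*% K
  fine_dataset(pos, frc,
               metadata = list(system = system$kind, sampler = "exact",
                               seed = seed))
}

# --- Langevin sampling of fine systems -------------------------------------

#' Langevin trajectory dataset from a fine-grained system
#'
#' Runs BAOAB Langevin dynamics on the fine-grained potential (same
#' integrator as the CG simulator, see [langevin_run()]), subsamples with the
#' configured stride, and records analytic forces per retained frame.
#'
#' @param system A `fine_system`.
#' @param n_steps Number of integration steps.
#' @param config An [integrator_config()] (its `n_steps` is overridden).
#' @param init Initial configuration matrix; default: origin.
#' @param seed Integer seed.
#' @return A [fine_dataset()] with sampler metadata.
#' @export
sample_fine_langevin <- function(system, n_steps, config, init = NULL,
                                 seed = 1) {
  if (is.null(init)) init <- matrix(0, system$n_particles, system$dim)
  init <- matrix(init, system$n_particles, system$dim)
  cfg <- config
  cfg$n_steps <- as.integer(n_steps)
  cfg$seed <- seed
  force_fn <- function(R) fine_forces(system, R)
  out <- .baoab_run(force_fn, NULL, init, cfg, kT = cfg$kT)
  m <- dim(out$positions)[1]
  frc <- array(0, dim = dim(out$positions))
  for (i in seq_len(m)) frc[i, , ] <- fine_forces(system, .frame(out$positions, i))
  fine_dataset(out$positions, frc,
               metadata = list(system = system$kind, sampler = "langevin",
                               seed = seed, n_steps = n_steps,
                               timestep = cfg$timestep, friction = cfg$friction))
}

#' Deliberately biased short-trajectory dataset
#'
#' Emulates training data drawn from short, unconverged MD: many short
#' Langevin trajectories seeded from chosen basins, whose empirical
#' distribution does not follow the Boltzmann weight of the potential of mean
#' force. Metadata records the per-basin frame fractions so the bias is
#' measurable against the quadrature equilibrium.
#'
#' @param system A `fine_system`.
#' @param basin_inits List of basins, each a list with `init` (configuration
#'   matrix), `n_traj` (number of trajectories) and optional `label`.
#' @param traj_len Frames retained per trajectory (after striding).
#' @param config An [integrator_config()]; `stride * traj_len` steps are run
#'   per trajectory.
#' @param seed Integer seed; trajectory seeds are derived from it.
#' @return A [fine_dataset()]; `metadata$basin_fractions` holds the realized
#'   per-basin frame shares.
#' @export
make_biased_dataset <- function(system, basin_inits, traj_len, config,
                                seed = 1) {
  if (length(basin_inits) == 0) stop("basin_inits must not be empty")
  n_steps <- config$stride * traj_len
  pos_list <- list(); frc_list <- list(); labels <- character(0)
  k <- 0
  for (b in seq_along(basin_inits)) {
    bi <- basin_inits[[b]]
    lab <- if (!is.null(bi$label)) bi$label else paste0("basin", b)
    nt <- bi$n_traj
    if (nt == 0) next
    for (t in seq_len(nt)) {
      k <- k + 1
      ds <- sample_fine_langevin(system, n_steps, config, init = bi$init,
                                 seed = derive_seed(seed, paste0("traj", k)))
      pos_list[[k]] <- ds$positions
      frc_list[[k]] <- ds$forces
      labels <- c(labels, rep(lab, dim(ds$positions)[1]))
    }
  }
  if (k == 0) stop("basin_inits produced no trajectories")
  pos <- abind_frames(pos_list)
  frc <- abind_frames(frc_list)
  fr <- table(labels) / length(labels)
  fine_dataset(pos, frc,
               metadata = list(system = system$kind, sampler = "biased_short_md",
                               seed = seed, traj_len = traj_len,
                               basin_fractions = as.list(fr),
                               frame_labels = labels))
}

# Concatenate a list of [m_i, n, d] arrays along the frame axis.
abind_frames <- function(lst) {
  n <- dim(lst[[1]])[2]; d <- dim(lst[[1]])[3]
  m <- sum(vapply(lst, function(a) dim(a)[1], 0L))
  out <- array(0, dim = c(m, n, d))
  at <- 0
  for (a in lst) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
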