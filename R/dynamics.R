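# CG simulators: BAOAB Langevin dynamics and parallel tempering with a
# geometric temperature ladder and Metropolis exchanges.
#
# BAOAB splitting is used throughout for its accurate configurational
# sampling at large timesteps. Internally everything is in reduced units
# (k_B T = 1 at the reference temperature); physical presets (fs, ps, K) are
# converted at the CLI layer.

#' Integrator configuration
#'
#' @param timestep Integration timestep (> 0, reduced units).
#' @param friction Langevin friction coefficient (> 0, inverse time).
#' @param kT Thermal energy (per-replica values are set by [pt_run()]).
#' @param n_steps Number of steps.
#' @param stride Frame-recording stride (>= 1).
#' @param seed Integer seed.
#' @return An `integrator_config`.
#' @export
integrator_config <- function(timestep, friction = 1, kT = 1, n_steps = 1000,
                              stride = 1, seed = 1) {
  stopifnot(timestep > 0, friction > 0, stride >= 1)
  structure(list(timestep = timestep, friction = friction, kT = kT,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 seed = seed),
            class = "integrator_config")
}

#' CG trajectory
#'
#' @param frames Array `[n, N, dim]`.
#' @param energies Optional per-frame potential energies.
#' @param temperature Simulation temperature (kT).
#' @param provenance List (potential checksum, config, seed).
#' @return A `cg_trajectory`.
#' @export
cg_trajectory <- function(frames, energies = NULL, temperature = 1,
                          provenance = list()) {
  .assert_finite(frames, "trajectory frames")
  structure(list(frames = frames, energies = energies,
                 temperature = temperature, provenance = provenance),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cg_trajectory: %d frames, %d sites, dim %d, kT = %g>\n",
              d[1], d[2], d[3], x$temperature))
  invisible(x)
}

# One BAOAB step; returns list(R, v). Draws exactly N*dim normals. The
# divergence check runs before the force evaluation so the caller's step
# label reaches the error message.
.baoab_step <- function(force_fn, R, v, f, dt, c1, c2, where = "step") {
  v <- v + 0.5 * dt * f
  R <- R + 0.5 * dt * v
  v <- c1 * v + c2 * matrix(rnorm(length(R)), nrow(R), ncol(R))
  R <- R + 0.5 * dt * v
  if (!all(is.finite(R)))
    stop(sprintf("integration diverged at %s", where))
  f <- force_fn(R)
  v <- v + 0.5 * dt * f
  list(R = R, v = v, f = f)
}

# Full BAOAB run; seeds the RNG from config$seed.
.baoab_run <- function(force_fn, energy_fn, R0, config, kT = config$kT) {
  dt <- config$timestep
  c1 <- exp(-config$friction * dt)
  c2 <- sqrt(kT * (1 - c1^2))
  set.seed(derive_seed(config$seed, "langevin"))
  R <- R0
  v <- sqrt(kT) * matrix(rnorm(length(R)), nrow(R), ncol(R))
  f <- force_fn(R)
  n_out <- config$n_steps %/% config$stride
  frames <- array(0, dim = c(n_out, nrow(R), ncol(R)))
  energies <- if (!is.null(energy_fn)) numeric(n_out) else NULL
  k <- 0
  for (step in seq_len(config$n_steps)) {
    st <- .baoab_step(force_fn, R, v, f, dt, c1, c2,
                      where = sprintf("step %d", step))
    R <- st$R; v <- st$v; f <- st$f
    if (step %% config$stride == 0) {
      k <- k + 1
      frames[k, , ] <- R
      if (!is.null(energies)) energies[k] <- energy_fn(R)
    }
  }
  list(positions = frames, energies = energies)
}

#' Langevin dynamics on a CG potential
#'
#' BAOAB-splitting Langevin integration of the learned CG potential, with
#' bit-reproducible trajectories under a fixed seed. Aborts with the step
#' index if a coordinate becomes non-finite.
#'
#' @param potential A [cg_potential()].
#' @param R_init Initial CG configuration `[N, dim]`.
#' @param config An [integrator_config()].
#' @return A [cg_trajectory()] with per-frame energies at the stride.
#' @export
langevin_run <- function(potential, R_init, config) {
  R_init <- as.matrix(R_init)
  .assert_finite(R_init, "R_init")
  out <- .baoab_run(function(R) cg_forces(potential, R),
                    function(R) cg_energy(potential, R),
                    R_init, config)
  cg_trajectory(out$positions, out$energies, temperature = config$kT,
                provenance = list(potential_checksum = .object_hash(potential),
                                  config = unclass(config),
                                  seed = config$seed))
}

#' Geometric temperature ladder
#'
#' `T_i = t_min (t_max/t_min)^{i/(n-1)}`, endpoints exact, constant ratio.
#'
#' @param t_min,t_max Ladder bounds (0 < t_min < t_max).
#' @param n Number of rungs (>= 2).
#' @return Ascending temperature vector.
#' @export
#' @examples
#' geometric_ladder(284.1, 362, 10)
geometric_ladder <- function(t_min, t_max, n) {
  if (!(t_min > 0 && t_max > t_min)) stop("require 0 < t_min < t_max")
  if (n < 2) stop("n must be >= 2")
  out <- t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1))
  out[1] <- t_min; out[n] <- t_max
  out
}

#' Metropolis exchange probability
#'
#' `min(1, exp((beta_i - beta_j)(u_i - u_j)))` for a replica swap.
#'
#' @param beta_i,beta_j Inverse temperatures (> 0).
#' @param u_i,u_j Potential energies.
#' @return Acceptance probability in `[0, 1]`.
#' @export
exchange_probability <- function(beta_i, beta_j, u_i, u_j) {
  stopifnot(beta_i > 0, beta_j > 0)
  min(1, exp((beta_i - beta_j) * (u_i - u_j)))
}

#' Replica ladder specification
#'
#' @param temperatures Strictly increasing kT values.
#' @param exchange_interval Steps between exchange attempts.
#' @return A `replica_ladder`.
#' @export
replica_ladder <- function(temperatures, exchange_interval = 20) {
  stopifnot(all(diff(temperatures) > 0) || length(temperatures) == 1,
            exchange_interval >= 1)
  structure(list(temperatures = temperatures,
                 betas = 1 / temperatures,
                 exchange_interval = as.integer(exchange_interval)),
            class = "replica_ladder")
}

#' Parallel-tempering Langevin run
#'
#' Replica-exchange Langevin dynamics: each rung integrates at its own
#' temperature with the shared BAOAB kernel; every `exchange_interval` steps
#' Metropolis swaps are attempted between adjacent pairs, alternating
#' even/odd pairings. Per-pair acceptance rates are reported; practitioners
#' monitor that all rates stay above ~0.3. With a single rung the run is
#' bit-identical to [langevin_run()] at the same seed.
#'
#' @param potential A [cg_potential()].
#' @param inits List of initial configurations, one per replica.
#' @param ladder A [replica_ladder()].
#' @param config An [integrator_config()] (its `kT` is ignored; rung
#'   temperatures are used).
#' @return List with `trajectories` (one [cg_trajectory()] per rung, frames
#'   by temperature) and an `acceptance` data frame (pair, attempts,
#'   accepted, rate).
#' @export
pt_run <- function(potential, inits, ladder, config) {
  temps <- ladder$temperatures
  nrep <- length(temps)
  stopifnot(length(inits) == nrep)
  dt <- config$timestep
  c1 <- exp(-config$friction * dt)
  c2 <- sqrt(temps * (1 - c1^2))
  force_fn <- function(R) cg_forces(potential, R)
  energy_fn <- function(R) cg_energy(potential, R)
  set.seed(derive_seed(config$seed, "langevin"))
  Rs <- lapply(inits, as.matrix)
  vs <- lapply(seq_len(nrep), function(k)
    sqrt(temps[k]) * matrix(rnorm(length(Rs[[k]])), nrow(Rs[[k]]), ncol(Rs[[k]])))
  fs <- lapply(Rs, force_fn)
  n_out <- config$n_steps %/% config$stride
  frames <- lapply(seq_len(nrep), function(k)
    array(0, dim = c(n_out, nrow(Rs[[k]]), ncol(Rs[[k]]))))
  energies <- lapply(seq_len(nrep), function(k) numeric(n_out))
  attempts <- integer(max(nrep - 1, 1)); accepted <- integer(max(nrep - 1, 1))
  parity <- 0L
  k_out <- 0
  for (step in seq_len(config$n_steps)) {
    for (k in seq_len(nrep)) {
      st <- .baoab_step(force_fn, Rs[[k]], vs[[k]], fs[[k]], dt, c1, c2[k],
                        where = sprintf("step %d (replica %d)", step, k))
      Rs[[k]] <- st$R; vs[[k]] <- st$v; fs[[k]] <- st$f
    }
    if (nrep > 1 && step %% ladder$exchange_interval == 0) {
      us <- vapply(Rs, energy_fn, 0)
      if (!all(is.finite(us))) stop("non-finite energy at exchange attempt")
      first <- if (parity == 0L) 1L else 2L
      pairs <- seq(first, nrep - 1, by = 2)
      for (i in pairs) {
        attempts[i] <- attempts[i] + 1L
        p <- exchange_probability(1 / temps[i], 1 / temps[i + 1],
                                  us[i], us[i + 1])
        if (runif(1) < p) {
          accepted[i] <- accepted[i] + 1L
          tmpR <- Rs[[i]]; Rs[[i]] <- Rs[[i + 1]]; Rs[[i + 1]] <- tmpR
          # rescale velocities to the new rung temperature
          sc <- sqrt(temps[i] / temps[i + 1])
          tmpv <- vs[[i]]
          vs[[i]] <- vs[[i + 1]] * sc
          vs[[i + 1]] <- tmpv / sc
          tmpf <- fs[[i]]; fs[[i]] <- fs[[i + 1]]; fs[[i + 1]] <- tmpf
          tmpu <- us[i]; us[i] <- us[i + 1]; us[i + 1] <- tmpu
        }
      }
      parity <- 1L - parity
    }
    if (step %% config$stride == 0) {
      k_out <- k_out + 1
      for (k in seq_len(nrep)) {
        frames[[k]][k_out, , ] <- Rs[[k]]
        energies[[k]][k_out] <- energy_fn(Rs[[k]])
      }
    }
  }
  trajs <- lapply(seq_len(nrep), function(k)
    cg_trajectory(frames[[k]], energies[[k]], temperature = temps[k],
                  provenance = list(config = unclass(config),
                                    seed = config$seed, rung = k)))
  acc <- if (nrep > 1) data.frame(pair = paste(seq_len(nrep - 1),
                                               seq(2, nrep), sep = "-"),
                                  attempts = attempts, accepted = accepted,
                                  rate = ifelse(attempts > 0,
                                                accepted / attempts, NA))
         else data.frame(pair = character(0), attempts = integer(0),
                         accepted = integer(0), rate = numeric(0))
  list(trajectories = trajs, acceptance = acc)
}
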