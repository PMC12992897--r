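test_that("chain coupling spec builds the documented precision matrix", {
  sys <- make_gaussian_network(2, coupling_spec = list(spring = 1, tether = 1))
  expect_equal(sys$params$K, matrix(c(2, -1, -1, 2), 2))
  expect_equal(sys$dim, 1L)
  expect_equal(sys$n_particles, 2L)
})

test_that("non-positive-definite couplings are rejected naming the eigenvalue", {
  K_bad <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3, -1
  expect_error(make_gaussian_network(2, coupling_spec = list(K = K_bad)),
               "positive definite.*-1", ignore.case = TRUE)
  expect_error(make_gaussian_network(2, coupling_spec = list(
    K = matrix(c(1, 0.5, 0.2, 1), 2))), "symmetric")
})

test_that("forces are the negative analytic gradient of the energy", {
  set.seed(4)
  sys5 <- make_gaussian_network(5, coupling_spec = list(spring = 1.7,
                                                        tether = 0.4))
  expect_lt(fd_force_error(sys5, rnorm(5)), 1e-6)
  chain <- make_double_well_chain()
  expect_lt(fd_force_error(chain, rnorm(chain$n_particles, sd = 0.5)), 1e-6)
  expect_lt(fd_force_error(make_double_well_chain(n_bath = 0),
                           rnorm(2)), 1e-6)
  # forces vanish at the origin of the quadratic network
  expect_equal(fine_forces(sys5, matrix(0, 5, 1)), matrix(0, 5, 1))
})

test_that("double-well bond force vanishes at the well bottom and barrier top", {
  sys <- make_double_well_chain(n_bath = 0, params = list(a = 6, d0 = 1))
  at_d <- function(d) fine_forces(sys, matrix(c(-d / 2, d / 2), 2, 1))
  expect_equal(at_d(1), matrix(0, 2, 1))
  expect_equal(at_d(0), matrix(0, 2, 1))
  expect_error(make_double_well_chain(params = list(a = -1)), "a must be")
  expect_error(make_double_well_chain(params = list(d0 = 0)), "d0 must be")
})

test_that("exact Gaussian sampler is reproducible and matches closed-form moments", {
  sys <- two_particle_system()
  d1 <- sample_gaussian_exact(sys, 50, seed = 9)
  d2 <- sample_gaussian_exact(sys, 50, seed = 9)
  expect_identical(d1$positions, d2$positions)
  expect_identical(d1$forces, d2$forces)
  expect_equal(dim(sample_gaussian_exact(sys, 1)$positions), c(1L, 2L, 1L))

  ds <- sample_gaussian_exact(sys, 1e5, seed = 2)
  X <- ds$positions[, , 1]
  Sref <- solve(sys$params$K)            # (1/3) [[2,1],[1,2]]
  Shat <- crossprod(X) / nrow(X)
  # CLT on second moments of a Gaussian: var(x_a x_b) = S_aa S_bb + S_ab^2
  for (a in 1:2) for (b in 1:2) {
    se <- sqrt((Sref[a, a] * Sref[b, b] + Sref[a, b]^2) / nrow(X))
    expect_lt(abs(Shat[a, b] - Sref[a, b]), 4 * se)
  }
  expect_error(sample_gaussian_exact(sys, 0), "n_frames")
})

test_that("Langevin fine sampler reproduces equipartition and determinism", {
  sys <- make_gaussian_network(2, coupling_spec = list(K = diag(2) * 2))
  cfg <- integrator_config(timestep = 0.02, friction = 1, n_steps = 1,
                           stride = 5)
  ds <- sample_fine_langevin(sys, 150000, cfg, seed = 3)
  v <- mean(apply(ds$positions[, , 1], 2, var))
  expect_lt(abs(v - 0.5) / 0.5, 0.03)    # var = kT / k = 1/2
  d1 <- sample_fine_langevin(sys, 500, cfg, seed = 8)
  d2 <- sample_fine_langevin(sys, 500, cfg, seed = 8)
  expect_identical(d1$positions, d2$positions)
})

test_that("short trajectories seeded in one basin stay there while equilibrium is split", {
  sys <- make_double_well_chain(n_bath = 0, params = list(a = 6, d0 = 1))
  cfg <- integrator_config(timestep = 0.01, friction = 1, n_steps = 1,
                           stride = 10)
  init <- matrix(c(0.5, -0.5), 2, 1)     # basin A: d = x2 - x1 = -1
  ds <- make_biased_dataset(sys, list(list(init = init, n_traj = 40,
                                           label = "A")),
                            traj_len = 25, cfg, seed = 12)
  d <- ds$positions[, 2, 1] - ds$positions[, 1, 1]
  expect_gt(mean(d < 0), 0.9)
  # equilibrium of the symmetric well splits 50/50 by quadrature
  orc <- quadrature_pmf(sys, "bond_displacement",
                        seq(-2, 2, length.out = 401))
  expect_equal(basin_probability(orc, 0), 0.5, tolerance = 1e-10)
  expect_equal(ds$metadata$basin_fractions$A, 1)
  expect_identical(unique(ds$metadata$frame_labels), "A")
  expect_error(make_biased_dataset(sys, list(), 10, cfg), "empty")
})

test_that("dataset container validates shapes and weights", {
  pos <- array(rnorm(12), dim = c(2, 3, 2))
  expect_error(fine_dataset(pos, array(0, dim = c(2, 3, 1))))
  expect_error(fine_dataset(pos, pos, weights = c(-1, 1)))
  expect_error(fine_dataset(pos, pos, weights = c(0, 0)), "zero")
  ds <- fine_dataset(pos, pos, weights = c(0.5, 2))
  expect_s3_class(ds, "fine_dataset")
})
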