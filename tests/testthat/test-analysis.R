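rotate2d <- function(R, angle) {
  Q <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  R %*% Q
}

test_that("collective variables have their defining closed-form values", {
  R <- matrix(c(0, 3, 0, 4), 2, 2)       # sites (0,0) and (3,4)
  arr <- array(R, dim = c(1, 2, 2))
  expect_equal(compute_cv(arr, cv_spec("distance", pair = c(1, 2))), 5)
  expect_equal(compute_cv(arr, cv_spec("radius_of_gyration")), 2.5)
  expect_equal(compute_cv(arr, cv_spec("linear_projection",
                                       w = c(1, -1, 0, 0))), -3)
  expect_error(cv_spec("distance"), "pair")
  expect_error(cv_spec("rmsd"), "reference")
})

test_that("RMSD is invariant to rigid rotation and translation of the frame", {
  set.seed(61)
  ref <- matrix(rnorm(10), 5, 2)
  moved <- rotate2d(ref, 0.7) + matrix(c(3, -2), 5, 2, byrow = TRUE)
  arr <- array(0, dim = c(2, 5, 2))
  arr[1, , ] <- ref
  arr[2, , ] <- moved
  v <- compute_cv(arr, cv_spec("rmsd", reference = ref))
  expect_lt(max(abs(v)), 1e-10)
  # a genuinely deformed frame has positive RMSD
  arr[2, , ] <- ref + rnorm(10, sd = 0.3)
  expect_gt(compute_cv(arr, cv_spec("rmsd", reference = ref))[2], 0.05)
})

test_that("the native-contact fraction is ~1 at the reference and drops on unfolding", {
  set.seed(62)
  ref <- matrix(rnorm(12), 6, 2)
  contacts <- rbind(c(1, 3), c(2, 5), c(4, 6))
  spec <- cv_spec("fraction_native_contacts", reference = ref,
                  contacts = contacts)
  arr <- array(0, dim = c(2, 6, 2))
  arr[1, , ] <- ref
  arr[2, , ] <- ref * 3                  # stretched: contacts broken
  q <- compute_cv(arr, spec)
  expect_gt(q[1], 0.99)
  expect_lt(q[2], 0.2)
})

test_that("histogram free energies are min-shifted with masked empty bins", {
  set.seed(63)
  x <- rnorm(20000)
  breaks <- seq(-5, 5, length.out = 51)
  fes <- histogram_fes(x, breaks)
  expect_equal(min(fes$free_energy[fes$mask]), 0)
  expect_true(any(!fes$mask))            # far tails unpopulated
  # the populated region tracks the quadratic reference
  sel <- fes$mask & abs(fes$mids) < 2
  expect_lt(mean(abs(fes$free_energy[sel] - 0.5 * fes$mids[sel]^2)), 0.1)
  # weights shift the surface: doubling half the data tilts the histogram
  fes_w <- histogram_fes(c(-1, 1), c(-2, 0, 2), weights = c(3, 1))
  expect_equal(diff(fes_w$free_energy), log(3))
})

test_that("2-D histograms and FES errors share binning and offset invariance", {
  set.seed(64)
  xy <- cbind(rnorm(5000), rnorm(5000))
  breaks <- list(seq(-4, 4, length.out = 21), seq(-4, 4, length.out = 21))
  fes <- histogram_fes(xy, breaks)
  expect_equal(dim(fes$free_energy), c(20L, 20L))
  expect_equal(fes_error(fes, fes), 0)
  # constant offsets do not change the error
  shifted <- fes
  shifted$free_energy <- fes$free_energy + 2
  expect_equal(fes_error(shifted, fes), 0)
  other <- histogram_fes(xy, list(seq(-4, 4, length.out = 11),
                                  seq(-4, 4, length.out = 11)))
  expect_error(fes_error(other, fes), "identical binning")
})

test_that("potential- and oracle-derived surfaces agree on a known well", {
  breaks <- seq(-2, 2, length.out = 41)
  pot <- harmonic_potential_for_fes <- cg_potential(
    trainable = trainable_energy("linear",
                                 feature_poly_projection(w = c(-1, 1),
                                                         powers = 2),
                                 params = 0.75))
  # embed(x) = (-x/2, x/2): projection w.R = x, so F(x) = 0.75 x^2
  fes_pot <- fes_from_potential(pot, breaks)
  mids <- (breaks[-1] + breaks[-41]) / 2
  orc <- pmf_oracle(mids, 0.75 * mids^2)
  fes_orc <- fes_from_oracle(orc, breaks)
  expect_lt(fes_error(fes_pot, fes_orc), 1e-10)
})

test_that("TICA recovers timescales and directions of a mixed OU process", {
  lag <- 5
  ou <- ou_mixture(2e5, lag, auto_slow = 0.9, auto_fast = 0.2, seed = 65)
  res <- tica(ou$series, lag = lag)
  expect_equal(res$eigenvalues[1], 0.9, tolerance = 0.02)
  expect_equal(res$eigenvalues[2], 0.2, tolerance = 0.05)
  # leading IC correlates with the latent slow coordinate
  ic1 <- (ou$series - matrix(res$mean, nrow(ou$series), 2,
                             byrow = TRUE)) %*% res$components[, 1]
  expect_gt(abs(cor(as.numeric(ic1), ou$slow)), 0.99)
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    expect_gt(res$components[which.max(abs(res$components[, j])), j], 0)
  }
})

test_that("TICA guards against singular covariances and short trajectories", {
  set.seed(66)
  x <- rnorm(500)
  degenerate <- cbind(x, x)               # rank-1 covariance
  expect_warning(tica(degenerate, lag = 2), "ridge|singular")
  expect_error(tica(matrix(rnorm(10), 5, 2), lag = 10), "longer than")
  expect_error(tica(matrix(rnorm(10), 5, 2), lag = 0), "lag")
  # multiple trajectories pool their statistics
  ou <- ou_mixture(4e4, 5, seed = 67)
  half <- list(ou$series[1:2e4, ], ou$series[2e4 + 1:2e4, ])
  r1 <- tica(ou$series, lag = 5)
  r2 <- tica(half, lag = 5)
  expect_equal(r1$eigenvalues[1], r2$eigenvalues[1], tolerance = 0.02)
})
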