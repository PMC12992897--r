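test_that("linear maps act per spatial dimension with shape checks", {
  expect_equal(apply_map(cg_mapping(matrix(c(0.5, 0.5), 1)),
                         matrix(c(1, 3), 2, 1)),
               matrix(2))
  expect_equal(apply_map(cg_mapping(matrix(c(1, 0), 1)),
                         matrix(c(1, 3), 2, 1)),
               matrix(1))
  mp <- cg_mapping(sites = c(1, 3), n_fine = 5)
  expect_true(mp$is_slice)
  expect_equal(apply_map(mp, matrix(0, 5, 2)), matrix(0, 2, 2))
  expect_error(apply_map(mp, matrix(0, 4, 2)), "does not match")
  expect_error(cg_mapping(matrix(0, 1, 2)), "nonzero")
})

test_that("the degenerate kernel returns coordinates unchanged with zero noise", {
  k0 <- noise_kernel(0)
  R0 <- matrix(rnorm(6), 3, 2)
  out <- sample_noise(k0, R0, seed = 1)
  expect_identical(out$R, R0)
  expect_identical(out$eps, R0 * 0)
  expect_error(noise_kernel(-1), "sigma2")
})

test_that("noise draws are seed-reproducible with the stated variance", {
  k <- noise_kernel(0.003)
  R0 <- array(0, dim = c(1e5, 1, 1))
  a <- sample_noise(k, R0, seed = 5)
  b <- sample_noise(k, R0, seed = 5)
  expect_identical(a$R, b$R)
  v <- var(as.numeric(a$R - R0))
  se <- 0.003 * sqrt(2 / (1e5 - 1))   # CLT for a chi-square variance
  expect_lt(abs(v - 0.003), 4 * se)
})

test_that("high noise levels trigger the documented warning", {
  expect_warning(noise_kernel(0.05), "detrimental")
  expect_silent(noise_kernel(0.05, warn = FALSE))
  expect_silent(noise_kernel(0.01))
})

test_that("kernel log-gradients have their Gaussian closed form", {
  mp <- cg_mapping(matrix(1, 1, 1))
  k <- noise_kernel(0.01)
  nb <- noise_force_blocks(k, mp, matrix(0), matrix(0.1))
  expect_equal(nb$gradR_logk, matrix(-10))
  expect_equal(nb$gradr_logk, matrix(10))
  # R = Mr: both blocks vanish
  nb0 <- noise_force_blocks(k, mp, matrix(0.3), matrix(0.3))
  expect_equal(nb0$gradR_logk, matrix(0))
  expect_error(noise_force_blocks(noise_kernel(0), mp, matrix(0), matrix(0)),
               "forces-only")
})

test_that("the two kernel gradient blocks satisfy gradr = -M' gradR exactly", {
  set.seed(6)
  mp <- cg_mapping(matrix(rnorm(10), 2, 5))
  k <- noise_kernel(0.003)
  r <- matrix(rnorm(15), 5, 3)
  R <- matrix(rnorm(6), 2, 3)
  nb <- noise_force_blocks(k, mp, r, R)
  expect_lt(max(abs(t(mp$matrix) %*% nb$gradR_logk + nb$gradr_logk)), 1e-12)
})

test_that("the kernel gradient at a noised point is exactly the denoising target", {
  set.seed(7)
  mp <- cg_mapping(matrix(rnorm(6), 2, 3))
  k <- noise_kernel(0.005, warn = FALSE)
  r <- matrix(rnorm(3), 3, 1)
  drawn <- sample_noise(k, mp$matrix %*% r, seed = 2)
  nb <- noise_force_blocks(k, mp, r, drawn$R)
  expect_equal(nb$gradR_logk, -drawn$eps / sqrt(k$sigma2), tolerance = 1e-12)
})

test_that("extended forces assemble the documented blocks and identities", {
  sys <- two_particle_system()
  mp <- two_particle_mapping()
  k <- noise_kernel(0.003)
  r <- matrix(c(0.4, -0.2), 2, 1)
  # R = Mr: noise parts vanish, r block is the bare MD force -Kr
  ef <- extended_forces(fine_forces(sys, r), k, mp, r, mp$matrix %*% r)
  expect_equal(ef$r_block, fine_forces(sys, r))
  expect_equal(ef$R_block, matrix(0))
  # random instance: r_block - md_force = -M' R_block
  R <- matrix(0.9)
  ef2 <- extended_forces(fine_forces(sys, r), k, mp, r, R)
  expect_equal(ef2$r_block - ef2$md_force, -t(mp$matrix) %*% ef2$R_block)
  expect_error(extended_forces(matrix(NaN, 2, 1), k, mp, r, R), "finite")
})

test_that("the mean kernel gradient given R is the score of the noised marginal", {
  sys <- two_particle_system()
  mp <- two_particle_mapping()
  s2 <- 0.1
  ds <- sample_gaussian_exact(sys, 4e4, seed = 13)
  R0 <- apply_map(mp, ds$positions)[, 1, 1]
  drawn <- sample_noise(noise_kernel(s2, warn = FALSE),
                        array(R0, dim = c(length(R0), 1, 1)), seed = 14)
  R <- as.numeric(drawn$R)
  g <- (R0 - R) / s2                     # gradR log kappa per frame
  fit <- origin_slope(R, g)
  expected <- -1 / (2 / 3 + s2)
  expect_lt(abs(fit$slope - expected), 3 * fit$se)
})

test_that("mapping definitions round-trip through the plain-text format", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("sites: [1, 3]", "n_fine: 5"), path)
  mp <- read_mapping(path)
  expect_true(mp$is_slice)
  expect_equal(dim(mp$matrix), c(2L, 5L))
  writeLines(c("n_fine: 3", "rows:",
               "  - indices: [1, 2]", "    weights: [0.5, 0.5]"), path)
  mp2 <- read_mapping(path)
  expect_equal(mp2$matrix, matrix(c(0.5, 0.5, 0), 1))
  expect_false(mp2$is_slice)
})
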