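test_that("slice force maps copy site forces and satisfy the constraint exactly", {
  mp <- two_particle_mapping()
  tm <- slice_map(mp)
  expect_equal(tm$matrix, matrix(c(1, 0), 1))
  expect_equal(tm$constraint_residual, 0)
  ident <- cg_mapping(diag(3))
  expect_equal(slice_map(ident)$matrix, diag(3))
  expect_error(slice_map(cg_mapping(matrix(c(0.5, 0.5), 1))),
               "optimize_atomistic_map")
})

test_that("force maps violating T M' = I are rejected at construction", {
  mp <- two_particle_mapping()
  expect_error(atomistic_force_map(matrix(c(0.9, 0), 1), mp), "T M' = I")
  tm <- atomistic_force_map(matrix(c(1, 0.37), 1), mp)
  expect_lt(tm$constraint_residual, 1e-8)
})

test_that("the variance-minimizing map reaches the closed-form optimum", {
  # For K = [[2,-1],[-1,2]], M = [1,0]: argmin <|Tf|^2> s.t. T1 = 1 is
  # T = [1, 1/2] with residual 3/2, vs 2 for the slice map (population values).
  sys <- two_particle_system()
  ds <- sample_gaussian_exact(sys, 2e4, seed = 21)
  mp <- two_particle_mapping()
  tm <- optimize_atomistic_map(ds, mp, l2_atom = 0)
  expect_equal(tm$matrix[1, 1], 1, tolerance = 1e-10)
  expect_equal(tm$matrix[1, 2], 0.5, tolerance = 0.05)
  r_opt <- residual_report(ds, mp, tm)$residual_msq
  r_slc <- residual_report(ds, mp, slice_map(mp))$residual_msq
  expect_lt(r_opt, r_slc)
  # heavy ridge pins the map to the slice reference
  tm_r <- optimize_atomistic_map(ds, mp, l2_atom = 1e8)
  expect_equal(tm_r$matrix, matrix(c(1, 0), 1), tolerance = 1e-3)
})

test_that("the noise-only map is exactly V = 0 and is flagged", {
  vm <- noise_only_map(2)
  expect_true(vm$is_noise_only)
  expect_equal(vm$matrix, matrix(0, 2, 2))
  expect_error(noise_stage_map(matrix(1), is_noise_only = TRUE), "V = 0")
  expect_error(noise_stage_map(matrix(NA_real_)), "finite")
})

test_that("the optimized noise stage beats nearby maps on its own objective", {
  sys <- two_particle_system()
  ds <- sample_gaussian_exact(sys, 5000, seed = 22)
  mp <- two_particle_mapping()
  tm <- optimize_atomistic_map(ds, mp, l2_atom = 0)
  k <- noise_kernel(0.1, warn = FALSE)
  vm <- optimize_noise_stage(ds, mp, tm, k, l2_noise = 0, n_noise_draws = 8,
                             seed = 3)
  obj <- function(v) residual_report(ds, mp, tm, noise_stage_map(matrix(v)),
                                     k, n_noise_draws = 8,
                                     seed = 99)$residual_msq
  v0 <- vm$matrix[1, 1]
  base <- obj(v0)
  for (dv in c(-0.1, -0.05, 0.05, 0.1)) expect_gt(obj(v0 + dv), base)
  # V = I cancels the pure-noise term entirely: target = T f_MD exactly
  ct <- compose_targets(ds, mp, tm, noise_stage_map(diag(1)), k, seed = 4)
  F0 <- ct$F0[ct$frame, , , drop = FALSE]
  expect_lt(max(abs(ct$target - F0)), 1e-12)
})

test_that("forces-only targets are the mapped coordinates and mapped forces", {
  sys <- two_particle_system()
  ds <- sample_gaussian_exact(sys, 50, seed = 23)
  mp <- two_particle_mapping()
  tm <- slice_map(mp)
  ct <- compose_targets(ds, mp, tm)
  expect_equal(ct$R, cgnoise:::.map_frames(mp$matrix, ds$positions))
  expect_equal(ct$target, cgnoise:::.map_frames(tm$matrix, ds$forces))
  expect_null(ct$eps)
  # noised path: shapes scale with n_draws and draws are seed-reproducible
  k <- noise_kernel(0.003)
  vm <- noise_only_map(1)
  c1 <- compose_targets(ds, mp, tm, vm, k, seed = 5, n_draws = 3)
  c2 <- compose_targets(ds, mp, tm, vm, k, seed = 5, n_draws = 3)
  expect_identical(c1$R, c2$R)
  expect_equal(dim(c1$R)[1], 150L)
  expect_equal(c1$target, -c1$eps / sqrt(0.003))
})

test_that("composed targets stay conditionally unbiased under a random noise stage", {
  sys <- two_particle_system()
  mp <- two_particle_mapping()
  tm <- slice_map(mp)
  s2 <- 0.05
  k <- noise_kernel(s2, warn = FALSE)
  ds <- sample_gaussian_exact(sys, 3e4, seed = 24)
  ct <- compose_targets(ds, mp, tm, noise_stage_map(matrix(0.37)), k,
                        seed = 25, n_draws = 2)
  fit <- origin_slope(as.numeric(ct$R), as.numeric(ct$target))
  expect_lt(abs(fit$slope - (-1 / (2 / 3 + s2))), 3 * fit$se)
})

test_that("residual reports match the analytic pure-noise magnitude", {
  # with V = 0 the target is -eps/sigma: <|target|^2> = N d / sigma2
  sys <- two_particle_system()
  ds <- sample_gaussian_exact(sys, 2000, seed = 26)
  mp <- two_particle_mapping()
  k <- noise_kernel(0.1, warn = FALSE)
  rep0 <- residual_report(ds, mp, slice_map(mp), noise_only_map(1), k,
                          n_noise_draws = 10, seed = 6)
  expect_equal(rep0$residual_msq, 1 / 0.1, tolerance = 0.05)
  expect_gte(rep0$residual_msq, 0)
})
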