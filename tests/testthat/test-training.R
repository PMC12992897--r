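make_training_fixture <- function(n_frames = 400, seed = 41) {
  sys <- two_particle_system()
  list(system = sys,
       dataset = sample_gaussian_exact(sys, n_frames, seed = seed),
       mapping = two_particle_mapping())
}

test_that("the combined loss with V = 0 equals the denoising loss exactly", {
  fx <- make_training_fixture()
  tm <- slice_map(fx$mapping)
  k <- noise_kernel(0.003)
  te <- trainable_energy("linear", feature_quadratic(1, 1), params = 0.8)
  pot <- cg_potential(trainable = te)
  for (nd in c(1, 3)) {
    lc <- loss_combined(pot, fx$dataset, fx$mapping, tm, noise_only_map(1), k,
                        seed = 42, n_draws = nd)
    ld <- loss_denoising(pot, fx$dataset, fx$mapping, k, seed = 42,
                         n_draws = nd)
    expect_lt(abs(lc - ld), 1e-12)
  }
})

test_that("the degenerate-kernel path reduces exactly to force matching", {
  fx <- make_training_fixture()
  tm <- slice_map(fx$mapping)
  te <- trainable_energy("linear", feature_quadratic(1, 1), params = 0.8)
  pot <- cg_potential(trainable = te)
  ct <- compose_targets(fx$dataset, fx$mapping, tm)
  direct <- mean((vapply(seq_len(dim(ct$R)[1]), function(i)
    cg_forces(pot, cgnoise:::.frame(ct$R, i)), 0) -
    as.numeric(ct$target))^2)
  expect_equal(loss_force_matching(pot, ct$R, ct$target), direct,
               tolerance = 1e-14)
  expect_error(loss_denoising(pot, fx$dataset, fx$mapping, noise_kernel(0)),
               "force_matching")
  expect_error(loss_combined(pot, fx$dataset, fx$mapping, tm,
                             noise_only_map(1), noise_kernel(0)),
               "force_matching")
})

test_that("stochastic training converges to the convex closed-form optimum", {
  fx <- make_training_fixture(3000, seed = 43)
  tm <- optimize_atomistic_map(fx$dataset, fx$mapping, l2_atom = 0)
  te <- trainable_energy("linear", feature_quadratic(1, 1))
  cf <- fit_linear_closed_form(te, fx$dataset, fx$mapping, t_atom = tm,
                               mode = "forces")
  cfg <- train_config("forces", batch_size = 128, learning_rate = 0.03,
                      max_epochs = 400, early_stop_patience = 60, seed = 44)
  fit <- fit_sgd(cg_potential(trainable = te), fx$dataset, fx$mapping,
                 t_atom = tm, config = cfg)
  expect_equal(fit$potential$trainable$params, cf$params, tolerance = 0.02)
  expect_equal(cf$params, 0.75, tolerance = 0.05)  # precision 1.5 => theta 3/4
  expect_lt(fit$history$selected_epoch, 400)
})

test_that("training runs are reproducible and a zero learning rate is inert", {
  fx <- make_training_fixture(300, seed = 45)
  tm <- slice_map(fx$mapping)
  k <- noise_kernel(0.003)
  te <- trainable_energy("linear", feature_quadratic(1, 1))
  cfg <- train_config("combined", sigma2 = 0.003, batch_size = 64,
                      learning_rate = 0.02, max_epochs = 5, seed = 46)
  f1 <- fit_sgd(cg_potential(trainable = te), fx$dataset, fx$mapping,
                t_atom = tm, kernel = k, config = cfg)
  f2 <- fit_sgd(cg_potential(trainable = te), fx$dataset, fx$mapping,
                t_atom = tm, kernel = k, config = cfg)
  expect_identical(f1$potential$trainable$params,
                   f2$potential$trainable$params)
  expect_identical(f1$history$selected_checksum, f2$history$selected_checksum)
  cfg0 <- train_config("combined", sigma2 = 0.003, learning_rate = 0,
                       max_epochs = 2, seed = 46)
  f0 <- fit_sgd(cg_potential(trainable = te), fx$dataset, fx$mapping,
                t_atom = tm, kernel = k, config = cfg0)
  expect_identical(f0$potential$trainable$params, te$params)
})

test_that("training configuration rejects inconsistent settings", {
  expect_error(train_config("noise"), "sigma2")
  expect_error(train_config("combined", sigma2 = 0), "sigma2")
  expect_error(train_config("forces", validation_fraction = 1))
  expect_silent(train_config("forces"))
})

test_that("the closed-form fit subtracts prior forces before fitting", {
  # data generated by u = 0.5 k x^2 with a known prior absorbing part of it
  sys <- make_gaussian_network(2, coupling_spec = list(K = diag(2) * 2))
  ds <- sample_gaussian_exact(sys, 5000, seed = 47)
  mp <- cg_mapping(diag(2))
  pr <- prior_terms(bonds = NULL)   # empty prior: no-op path
  te <- trainable_energy("linear", feature_quadratic(2, 1))
  fit <- fit_linear_closed_form(te, ds, mp, t_atom = slice_map(mp),
                                mode = "forces", priors = pr)
  P <- quadratic_params_to_precision(fit$params, te$spec)
  expect_equal(P, diag(2) * 2, tolerance = 0.1)
  expect_gte(fit$residual_msq, 0)
})
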