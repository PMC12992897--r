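fd_feature_jacobian <- function(R, spec, h = 1e-6) {
  v <- cgnoise:::.flatten(as.matrix(R))
  J <- matrix(0, spec$n_features, length(v))
  for (q in seq_along(v)) {
    vp <- v; vm <- v
    vp[q] <- vp[q] + h; vm[q] <- vm[q] - h
    Rp <- matrix(vp, nrow = nrow(as.matrix(R)))
    Rm <- matrix(vm, nrow = nrow(as.matrix(R)))
    J[, q] <- (feature_basis(Rp, spec) - feature_basis(Rm, spec)) / (2 * h)
  }
  J
}

test_that("feature jacobians match finite differences for every basis family", {
  set.seed(31)
  R <- matrix(rnorm(6), 3, 2)
  specs <- list(
    feature_quadratic(3, 2),
    feature_poly_projection(w = rnorm(6), powers = c(1, 2, 4)),
    feature_rbf_projection(w = rnorm(6), centers = c(-1, 0, 1), width = 0.7),
    feature_rbf_distance(pairs = rbind(c(1, 2), c(2, 3)),
                         centers = c(0.5, 1.5), width = 0.5))
  for (spec in specs) {
    J <- cgnoise:::.feature_jacobian(R, spec)
    expect_lt(max(abs(J - fd_feature_jacobian(R, spec))), 1e-6)
  }
  expect_error(feature_rbf_distance(rbind(c(1, 2)), 1, width = 0), "width")
})

test_that("trainable forces are the negative gradient of the trainable energy", {
  set.seed(32)
  R <- matrix(rnorm(6), 3, 2)
  spec <- feature_rbf_distance(pairs = rbind(c(1, 2), c(1, 3)),
                               centers = c(0.5, 1, 1.5), width = 0.4)
  for (form in c("linear", "mlp")) {
    te <- trainable_energy(form, spec, seed = 2)
    if (form == "linear") te$params <- rnorm(spec$n_features)
    pot <- cg_potential(trainable = te)
    f <- cg_forces(pot, R)
    fd <- R
    h <- 1e-5
    for (i in 1:3) for (j in 1:2) {
      Rp <- R; Rm <- R
      Rp[i, j] <- Rp[i, j] + h; Rm[i, j] <- Rm[i, j] - h
      fd[i, j] <- -(cg_energy(pot, Rp) - cg_energy(pot, Rm)) / (2 * h)
    }
    expect_lt(max(abs(f - fd)), 1e-8)
  }
})

test_that("analytic parameter gradients of the force loss match finite differences", {
  set.seed(33)
  spec <- feature_rbf_projection(w = c(-1, 1), centers = c(-1, 0, 1),
                                 width = 0.6)
  for (form in c("linear", "mlp")) {
    te <- trainable_energy(form, spec, hidden = 4, seed = 3)
    if (form == "linear") te$params <- rnorm(spec$n_features)
    pot <- cg_potential(trainable = te)
    R <- array(rnorm(2 * 2 * 1), dim = c(2, 2, 1))
    tgt <- array(rnorm(4), dim = c(2, 2, 1))
    gl <- cgnoise:::.batch_loss_grad(pot, te, te$params, R, tgt)
    num <- vapply(seq_along(te$params), function(p) {
      h <- 1e-6
      tp <- te; tm <- te
      tp$params[p] <- tp$params[p] + h
      tm$params[p] <- tm$params[p] - h
      (cgnoise:::.batch_loss_grad(pot, tp, tp$params, R, tgt)$loss -
       cgnoise:::.batch_loss_grad(pot, tm, tm$params, R, tgt)$loss) / (2 * h)
    }, 0)
    expect_lt(max(abs(gl$grad - num)), 1e-8)
  }
})

test_that("prior terms produce consistent energies, forces and guard rails", {
  pr <- prior_terms(
    bonds = data.frame(i = 1, j = 2, k = 3, r0 = 1),
    repulsion = list(prefactor = 0.5, scale = 0.8, exponent = 6,
                     pairs = rbind(c(1, 3))))
  pot <- cg_potential(priors = pr)
  set.seed(34)
  R <- matrix(rnorm(9, sd = 2), 3, 3)
  f <- cg_forces(pot, R)
  fd <- R
  h <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    Rp <- R; Rm <- R
    Rp[i, j] <- Rp[i, j] + h; Rm[i, j] <- Rm[i, j] - h
    fd[i, j] <- -(cg_energy(pot, Rp) - cg_energy(pot, Rm)) / (2 * h)
  }
  expect_lt(max(abs(f - fd)), 1e-6)
  # coincident sites: capped with a warning instead of Inf
  Rc <- R; Rc[3, ] <- Rc[1, ]
  expect_warning(u <- cg_energy(pot, Rc), "coincident")
  expect_true(is.finite(u))
  expect_error(prior_terms(bonds = data.frame(i = 1, j = 2, k = -1, r0 = 1)))
})

test_that("moment-matched bond priors recover the noised bond statistics", {
  # 1-D Gaussian bond with Var(d) = 1/4: k = 1/(1/4 + sigma2), oracle values
  set.seed(35)
  m <- 2e5
  d <- 2 + 0.5 * rnorm(m)
  pos <- array(0, dim = c(m, 2, 1))
  pos[, 2, 1] <- d
  pr0 <- fit_priors(pos, rbind(c(1, 2)))
  expect_equal(pr0$bonds$k, 4, tolerance = 0.05)
  expect_equal(pr0$bonds$r0, 2, tolerance = 0.01)
  prn <- fit_priors(pos, rbind(c(1, 2)), kernel = noise_kernel(0.1, warn = FALSE),
                    seed = 4)
  expect_equal(prn$bonds$k, 1 / (0.25 + 0.1), tolerance = 0.05)
  expect_error(fit_priors(pos[1:50, , , drop = FALSE], rbind(c(1, 2))),
               "100 frames")
  same <- array(1, dim = c(200, 2, 1))
  expect_error(fit_priors(same, rbind(c(1, 2))), "zero-variance")
})

test_that("parameter replacement validates the trainable layout", {
  te <- trainable_energy("linear", feature_quadratic(1, 1))
  pot <- cg_potential(trainable = te)
  pot2 <- set_params(pot, 2)
  expect_equal(cg_energy(pot2, matrix(1.5)), 2 * 1.5^2)
  expect_error(set_params(pot, c(1, 2)))
  expect_error(set_params(cg_potential(), 1))
})
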