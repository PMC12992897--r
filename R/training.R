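# Training: the three loss modes (forces, noise, combined), ADAM
# optimization with per-batch noise augmentation and validation-based model
# selection, and an exact closed-form path for linear-in-parameters models.
#
# Loss normalization: mean over frames, noise draws, sites and spatial
# dimensions, so losses are comparable across system sizes. The two
# reductions of the combined loss are exact in code: with the noise-only map
# it equals the single-level denoising score-matching loss sample by sample,
# and with the degenerate kernel it equals the plain force-matching loss.

#' Training configuration
#'
#' @param mode `"forces"`, `"noise"` or `"combined"`.
#' @param sigma2 Noise level; ignored (and must not be relied on) in
#'   `forces` mode.
#' @param batch_size Frames per batch (>= 1).
#' @param learning_rate ADAM step size.
#' @param max_epochs Maximum epochs.
#' @param validation_fraction Fraction of frames held out, in (0, 1).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param seed Seed controlling the split, shuffling and noise draws.
#' @param n_noise_draws Noise draws per frame and epoch.
#' @return A `train_config`.
#' @export
train_config <- function(mode = c("forces", "noise", "combined"),
                         sigma2 = NULL, batch_size = 64, learning_rate = 0.01,
                         max_epochs = 100, validation_fraction = 0.1,
                         early_stop_patience = 10, seed = 1,
                         n_noise_draws = 1) {
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1, validation_fraction > 0, validation_fraction < 1)
  if (mode != "forces" && (is.null(sigma2) || sigma2 <= 0))
    stop("noise and combined modes require sigma2 > 0")
  structure(list(mode = mode, sigma2 = sigma2, batch_size = batch_size,
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 validation_fraction = validation_fraction,
                 early_stop_patience = early_stop_patience, seed = seed,
                 n_noise_draws = n_noise_draws),
            class = "train_config")
}

# Mean squared force error over a set of (R, target) rows.
.mse_forces <- function(potential, R, target) {
  m <- dim(R)[1]
  if (m < 1) stop("empty batch")
  tot <- 0
  for (i in seq_len(m)) {
    Fp <- cg_forces(potential, .frame(R, i))
    tot <- tot + sum((Fp - .frame(target, i))^2)
  }
  tot / length(target)
}

#' Force-matching loss
#'
#' Mean squared norm of `F_theta(R0) - F0` (mean over frames, sites and
#' dimensions), with targets precomposed in forces-only mode.
#'
#' @param potential A [cg_potential()].
#' @param R0 Mapped coordinates `[m, N, dim]`.
#' @param F0 Mapped force targets, same shape.
#' @return Scalar loss.
#' @export
loss_force_matching <- function(potential, R0, F0) {
  .mse_forces(potential, R0, F0)
}

#' Single-level denoising score-matching loss
#'
#' Mean squared norm of `F_theta(R0 + sigma eps) - (-eps/sigma)` with fresh
#' standard-normal noise per call (seeded).
#'
#' @param potential A [cg_potential()].
#' @param dataset A [fine_dataset()].
#' @param mapping A [cg_mapping()].
#' @param kernel A [noise_kernel()] with `sigma2 > 0`.
#' @param seed Optional seed for the draws.
#' @param n_draws Noise draws per frame.
#' @return Scalar loss.
#' @export
loss_denoising <- function(potential, dataset, mapping, kernel, seed = NULL,
                           n_draws = 1) {
  if (kernel$sigma2 == 0) stop("sigma2 = 0: use loss_force_matching")
  R0 <- .map_frames(mapping$matrix, dataset$positions)
  m <- dim(R0)[1]; N <- dim(R0)[2]; d <- dim(R0)[3]
  sig <- sqrt(kernel$sigma2)
  .maybe_seed(seed)
  eps <- array(rnorm(m * N * d * n_draws), dim = c(m * n_draws, N, d))
  idx <- rep(seq_len(m), times = n_draws)
  R <- R0[idx, , , drop = FALSE] + sig * eps
  .mse_forces(potential, R, -eps / sig)
}

#' Combined force-and-noise loss
#'
#' Mean squared norm of `F_theta(R) - target` with targets from
#' [compose_targets()] over frames and fresh noise draws. With the noise-only
#' map this equals [loss_denoising()] sample by sample; with `sigma2 = 0` the
#' caller is directed to [loss_force_matching()].
#'
#' @param potential A [cg_potential()].
#' @param dataset A [fine_dataset()].
#' @param mapping A [cg_mapping()].
#' @param t_atom An `atomistic_force_map`.
#' @param v_map A `noise_stage_map`.
#' @param kernel A [noise_kernel()] with `sigma2 > 0`.
#' @param seed Optional seed.
#' @param n_draws Noise draws per frame.
#' @return Scalar loss.
#' @export
loss_combined <- function(potential, dataset, mapping, t_atom, v_map, kernel,
                          seed = NULL, n_draws = 1) {
  if (kernel$sigma2 == 0) stop("sigma2 = 0: use loss_force_matching")
  ct <- compose_targets(dataset, mapping, t_atom, v_map, kernel,
                        seed = seed, n_draws = n_draws)
  .mse_forces(potential, ct$R, ct$target)
}

#' Train history
#'
#' @param train,validation Per-epoch losses.
#' @param selected_epoch Epoch achieving the minimum validation loss.
#' @param selected_checksum md5 of the selected parameter vector.
#' @return A `train_history` data frame with attributes.
#' @keywords internal
.train_history <- function(train, validation, selected_epoch, params) {
  h <- data.frame(epoch = seq_along(train), train = train,
                  validation = validation)
  structure(list(history = h, selected_epoch = selected_epoch,
                 selected_checksum = .object_hash(params)),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history: %d epochs, selected epoch %d (val loss %.6g)>\n",
              nrow(x$history), x$selected_epoch,
              x$history$validation[x$selected_epoch]))
  invisible(x)
}

#' Stochastic training with ADAM
#'
#' Splits frames into train/validation by a seeded permutation, minimizes
#' the configured loss by adaptive-moment gradient descent with fresh noise
#' per batch (noise and combined modes), evaluates the validation loss each
#' epoch on a frozen set of validation noise draws, and returns the
#' parameters of the epoch with the lowest validation loss. Fully
#' reproducible under the config seed.
#'
#' @param potential A [cg_potential()] with a trainable part.
#' @param dataset A [fine_dataset()].
#' @param mapping A [cg_mapping()].
#' @param t_atom An `atomistic_force_map` (forces/combined modes).
#' @param v_map A `noise_stage_map` (combined mode).
#' @param kernel A [noise_kernel()] (noise/combined modes).
#' @param config A [train_config()].
#' @return List with the trained `potential` and a `train_history`.
#' @export
fit_sgd <- function(potential, dataset, mapping, t_atom = NULL, v_map = NULL,
                    kernel = NULL, config) {
  stopifnot(!is.null(potential$trainable))
  mode <- config$mode
  m <- dim(dataset$positions)[1]
  set.seed(derive_seed(config$seed, "split"))
  perm <- sample.int(m)
  n_val <- max(1L, floor(config$validation_fraction * m))
  if (n_val >= m) stop("validation split leaves no training frames")
  val_idx <- perm[seq_len(n_val)]
  trn_idx <- perm[-seq_len(n_val)]
  sub <- function(idx) fine_dataset(
    dataset$positions[idx, , , drop = FALSE],
    dataset$forces[idx, , , drop = FALSE])
  ds_trn <- sub(trn_idx); ds_val <- sub(val_idx)
  if (mode == "combined" && is.null(v_map))
    v_map <- noise_only_map(nrow(mapping$matrix))
  if (mode != "forces" && (is.null(kernel) || kernel$sigma2 <= 0))
    stop("noise/combined modes require a kernel with sigma2 > 0")
  # frozen validation targets for comparable model selection across epochs
  val_targets <- switch(mode,
    forces = compose_targets(ds_val, mapping, t_atom),
    noise = {
      ct <- compose_targets(ds_val, mapping, slice_like(mapping),
                            noise_only_map(nrow(mapping$matrix)), kernel,
                            seed = derive_seed(config$seed, "valnoise"),
                            n_draws = config$n_noise_draws)
      ct
    },
    combined = compose_targets(ds_val, mapping, t_atom, v_map, kernel,
                               seed = derive_seed(config$seed, "valnoise"),
                               n_draws = config$n_noise_draws))
  trn_fixed <- if (mode == "forces")
    compose_targets(ds_trn, mapping, t_atom) else NULL

  te <- potential$trainable
  theta <- te$params
  mu <- numeric(length(theta)); nu <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t_step <- 0
  best_val <- Inf; best_theta <- theta; best_epoch <- 1L
  tr_loss <- numeric(0); va_loss <- numeric(0)
  set.seed(derive_seed(config$seed, "epochs"))
  n_trn <- length(trn_idx)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_trn)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bt in batches) {
      rows <- switch(mode,
        forces = list(R = trn_fixed$R[bt, , , drop = FALSE],
                      target = trn_fixed$target[bt, , , drop = FALSE]),
        noise = {
          ct <- compose_targets(sub(trn_idx[bt]), mapping,
                                slice_like(mapping),
                                noise_only_map(nrow(mapping$matrix)), kernel,
                                n_draws = config$n_noise_draws)
          list(R = ct$R, target = ct$target)
        },
        combined = {
          ct <- compose_targets(sub(trn_idx[bt]), mapping, t_atom, v_map,
                                kernel, n_draws = config$n_noise_draws)
          list(R = ct$R, target = ct$target)
        })
      gl <- .batch_loss_grad(potential, te, theta, rows$R, rows$target)
      if (!is.finite(gl$loss))
        stop(sprintf("non-finite loss at epoch %d", epoch))
      ep_loss <- ep_loss + gl$loss * dim(rows$R)[1]
      ep_n <- ep_n + dim(rows$R)[1]
      if (config$learning_rate > 0) {
        t_step <- t_step + 1
        mu <- b1 * mu + (1 - b1) * gl$grad
        nu <- b2 * nu + (1 - b2) * gl$grad^2
        mhat <- mu / (1 - b1^t_step)
        vhat <- nu / (1 - b2^t_step)
        theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    te$params <- theta
    pot_now <- potential; pot_now$trainable <- te
    vl <- .mse_forces(pot_now, val_targets$R, val_targets$target)
    tr_loss <- c(tr_loss, ep_loss / ep_n)
    va_loss <- c(va_loss, vl)
    if (vl < best_val) {
      best_val <- vl; best_theta <- theta; best_epoch <- epoch
    }
    if (epoch - best_epoch >= config$early_stop_patience) break
  }
  te$params <- best_theta
  potential$trainable <- te
  list(potential = potential,
       history = .train_history(tr_loss, va_loss, best_epoch, best_theta))
}

# Identity atomistic map placeholder used when only the noise target matters.
slice_like <- function(mapping) {
  N <- nrow(mapping$matrix)
  if (mapping$is_slice) return(slice_map(mapping))
  # any T with T M' = I works here since the atomistic block is unused (V=0)
  atomistic_force_map(solve(mapping$matrix %*% t(mapping$matrix),
                            mapping$matrix), mapping)
}

# loss + parameter gradient over a batch (trainable part only).
.batch_loss_grad <- function(potential, te, theta, R, target) {
  te$params <- theta
  m <- dim(R)[1]
  cnorm <- 1 / length(target)
  grad <- numeric(length(theta)); loss <- 0
  for (i in seq_len(m)) {
    Ri <- .frame(R, i)
    Fp <- .prior_force(potential$priors, Ri) + .te_force(te, Ri)
    res <- Fp - .frame(target, i)
    loss <- loss + sum(res^2)
    g_res <- 2 * cnorm * .flatten(res)
    grad <- grad + .te_force_param_grad(te, Ri, g_res)
  }
  list(loss = loss * cnorm, grad = grad)
}

#' Exact closed-form fit for linear-basis models
#'
#' For a linear-in-parameters trainable energy all three losses are convex
#' quadratics in `theta`; this solves the least-squares problem exactly with
#' fixed, pre-drawn noise. Serves as the convex oracle for [fit_sgd()] and as
#' the fast deterministic training path.
#'
#' @param trainable A linear [trainable_energy()].
#' @param dataset A [fine_dataset()].
#' @param mapping A [cg_mapping()].
#' @param t_atom,v_map,kernel Force-map stages as in [loss_combined()];
#'   unused pieces may be `NULL` depending on `mode`.
#' @param mode `"forces"`, `"noise"` or `"combined"`.
#' @param seed Seed for the frozen noise draws.
#' @param n_draws Noise draws per frame.
#' @param ridge Optional ridge on the normal equations (default 0: exact
#'   least squares; singular designs fall back to the minimum-norm solution
#'   with a warning).
#' @param priors Optional [prior_terms()] whose forces are subtracted from
#'   the targets before fitting.
#' @return List with `params`, the assembled `potential` and the residual
#'   mean square.
#' @export
fit_linear_closed_form <- function(trainable, dataset, mapping, t_atom = NULL,
                                   v_map = NULL, kernel = NULL,
                                   mode = c("forces", "noise", "combined"),
                                   seed = 1, n_draws = 1, ridge = 0,
                                   priors = NULL) {
  mode <- match.arg(mode)
  stopifnot(trainable$form == "linear")
  if (mode != "forces" && (is.null(kernel) || kernel$sigma2 <= 0))
    stop("noise/combined modes require a kernel with sigma2 > 0")
  N <- nrow(mapping$matrix)
  ct <- switch(mode,
    forces = compose_targets(dataset, mapping, t_atom),
    noise = compose_targets(dataset, mapping,
                            if (is.null(t_atom)) slice_like(mapping) else t_atom,
                            noise_only_map(N), kernel, seed = seed,
                            n_draws = n_draws),
    combined = compose_targets(dataset, mapping, t_atom, v_map, kernel,
                               seed = seed, n_draws = n_draws))
  m <- dim(ct$R)[1]
  D <- dim(ct$R)[2] * dim(ct$R)[3]
  P <- trainable$spec$n_features
  B <- matrix(0, m * D, P)
  y <- numeric(m * D)
  for (i in seq_len(m)) {
    Ri <- .frame(ct$R, i)
    J <- .feature_jacobian(Ri, trainable$spec)
    rows <- (i - 1) * D + seq_len(D)
    B[rows, ] <- -t(J)
    ti <- .flatten(.frame(ct$target, i))
    if (!is.null(priors)) ti <- ti - .flatten(.prior_force(priors, Ri))
    y[rows] <- ti
  }
  theta <- as.numeric(.pinv_solve(B, y, ridge = ridge,
                                  context = "linear training design"))
  trainable$params <- theta
  pot <- cg_potential(priors = priors, trainable = trainable)
  list(params = theta, potential = pot,
       residual_msq = mean((B %*% theta - y)^2))
}
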