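# Linear force maps projecting extended-system forces to CG training targets.
#
# Two sequential linear stages:
#   1. an atomistic stage T with the consistency constraint T M' = I,
#      optimized as an equality-constrained ridge least-squares problem that
#      minimizes the mean squared mapped force <|T f|^2>;
#   2. a CG-level noise stage V applied to the summed block
#      (T f_MD + eps/sigma), optimized by ridge regression against the pure
#      denoising target -eps/sigma.
# V = 0 recovers the noise-only target; the per-frame target is
#   target = -eps/sigma + V (T f_MD + eps/sigma),
# which is conditionally unbiased for the noised mean force for ANY finite V
# as long as T M' = I: V trades variance, never bias.

#' Atomistic-stage force map
#'
#' @param matrix Coefficients `T` (`N` CG sites by `n` fine particles).
#' @param mapping The [cg_mapping()] the constraint is checked against.
#' @param l2 Ridge strength used at build time (recorded).
#' @return An `atomistic_force_map` with the recorded constraint residual
#'   `max |T M' - I|`; building fails if it exceeds 1e-8.
#' @export
atomistic_force_map <- function(matrix, mapping, l2 = 0) {
  matrix <- as.matrix(matrix)
  .assert_finite(matrix, "force map")
  res <- max(abs(matrix %*% t(mapping$matrix) - diag(nrow(matrix))))
  if (res > 1e-8)
    stop(sprintf("consistency constraint T M' = I violated (residual %.3g)", res))
  structure(list(matrix = unname(matrix), constraint_residual = res, l2 = l2),
            class = "atomistic_force_map")
}

#' Slice force map
#'
#' For a slice CG map each site copies the force of its own particle:
#' `T = M`, satisfying `T M' = I` trivially.
#'
#' @param mapping A slice [cg_mapping()].
#' @return An `atomistic_force_map`.
#' @export
slice_map <- function(mapping) {
  if (!mapping$is_slice)
    stop("mapping is not a slice map; use optimize_atomistic_map")
  atomistic_force_map(mapping$matrix, mapping, l2 = 0)
}

#' Variance-minimizing atomistic force map
#'
#' Solves `argmin_T <|T f|^2> + l2_atom |T - T_ref|^2` subject to
#' `T M' = I`, row by row through the KKT system of the equality-constrained
#' ridge least-squares problem. `T_ref` defaults to the slice map when the
#' mapping is a slice (else zero). The force second-moment matrix is
#' accumulated over frames and spatial dimensions of the dataset.
#'
#' @param dataset A [fine_dataset()] with force labels.
#' @param mapping A [cg_mapping()].
#' @param l2_atom Ridge strength toward `T_ref` (default 1e3, the value used
#'   for atomistic contributions with forces in physical units; set 0 for the
#'   unregularized optimum).
#' @param t_ref Optional reference map matrix.
#' @return An `atomistic_force_map`.
#' @export
optimize_atomistic_map <- function(dataset, mapping, l2_atom = 1e3,
                                   t_ref = NULL) {
  M <- mapping$matrix
  N <- nrow(M); n <- ncol(M)
  f <- dataset$forces
  m <- dim(f)[1]; d <- dim(f)[3]
  C <- matrix(0, n, n)
  for (j in seq_len(d)) C <- C + crossprod(f[, , j]) / m
  if (is.null(t_ref)) t_ref <- if (mapping$is_slice) M else matrix(0, N, n)
  A <- C + l2_atom * diag(n)
  # KKT solved for the deviation from the reference map (T = t_ref + D) by
  # Schur-complement elimination against A, which stays well conditioned for
  # any ridge strength
  AiMt <- tryCatch(solve(A, t(M)), error = function(e) NULL)
  if (is.null(AiMt))
    stop("normal equations are rank deficient; raise l2_atom")
  Airhs <- solve(A, -C %*% t(t_ref))
  S <- M %*% AiMt
  B <- diag(N) - M %*% t(t_ref)
  Lam <- solve(S, M %*% Airhs - B)
  D <- Airhs - AiMt %*% Lam
  atomistic_force_map(t_ref + t(D), mapping, l2 = l2_atom)
}

#' Noise-stage force map
#'
#' @param V Coefficient matrix applied to the summed block
#'   `T f_MD + eps/sigma` (`N x N`).
#' @param l2 Ridge strength used (recorded).
#' @param is_noise_only Flag; `TRUE` forces `V = 0` (the pure denoising
#'   target, `T_noise`).
#' @return A `noise_stage_map`.
#' @export
noise_stage_map <- function(V, l2 = 0, is_noise_only = FALSE) {
  V <- as.matrix(V)
  .assert_finite(V, "noise-stage map")
  if (is_noise_only && any(V != 0)) stop("noise-only map must have V = 0")
  structure(list(matrix = unname(V), l2 = l2, is_noise_only = is_noise_only),
            class = "noise_stage_map")
}

#' Noise-only force map (T_noise)
#'
#' With `V = 0` the training target reduces to the pure denoising target
#' `-eps/sigma`: training uses only noise-related information and the
#' combined loss coincides with single-level denoising score matching.
#'
#' @param n_sites Number of CG sites.
#' @return A `noise_stage_map` flagged `is_noise_only`.
#' @export
noise_only_map <- function(n_sites) {
  noise_stage_map(matrix(0, n_sites, n_sites), l2 = Inf, is_noise_only = TRUE)
}

#' Optimize the noise-stage map
#'
#' Stage-2 ridge regression. With per-frame, per-draw blocks
#' `g = -eps/sigma` and `h = T f_MD + eps/sigma`, solves
#' `V = argmin <|g + V h|^2> + l2_noise |V|^2`, i.e. in closed form
#' `V = -<g h'> (<h h'> + l2_noise I)^-1`, with moments accumulated over
#' frames, seeded noise draws and spatial dimensions.
#'
#' @param dataset A [fine_dataset()].
#' @param mapping A [cg_mapping()].
#' @param t_atom An `atomistic_force_map`.
#' @param kernel A [noise_kernel()] with `sigma2 > 0`.
#' @param l2_noise Ridge strength (default 5, the value used for post-map
#'   noise contributions).
#' @param n_noise_draws Noise draws per frame.
#' @param seed Integer seed for the draws.
#' @return A `noise_stage_map`.
#' @export
optimize_noise_stage <- function(dataset, mapping, t_atom, kernel,
                                 l2_noise = 5, n_noise_draws = 4, seed = 1) {
  if (kernel$sigma2 == 0)
    stop("sigma2 = 0: the noise stage requires a non-degenerate kernel")
  m <- dim(dataset$positions)[1]
  if (m < 1) stop("empty dataset")
  F0 <- .map_frames(t_atom$matrix, dataset$forces)   # [m, N, d]
  N <- dim(F0)[2]; d <- dim(F0)[3]
  sig <- sqrt(kernel$sigma2)
  .maybe_seed(seed)
  Cgh <- matrix(0, N, N); Chh <- matrix(0, N, N)
  cnt <- 0
  for (k in seq_len(n_noise_draws)) {
    eps <- array(rnorm(m * N * d), dim = c(m, N, d))
    for (j in seq_len(d)) {
      g <- -t(eps[, , j]) / sig              # N x m
      h <- t(F0[, , j]) + t(eps[, , j]) / sig
      Cgh <- Cgh + tcrossprod(g, h)
      Chh <- Chh + tcrossprod(h, h)
      cnt <- cnt + m
    }
  }
  Cgh <- Cgh / cnt; Chh <- Chh / cnt
  V <- -Cgh %*% solve(Chh + l2_noise * diag(N))
  noise_stage_map(V, l2 = l2_noise, is_noise_only = FALSE)
}

#' Compose per-frame CG training targets
#'
#' The training procedure: map each frame (`R0 = M r`), project the
#' atomistic forces (`F0 = T f_MD`), draw noised counterparts
#' (`R = R0 + sigma eps`), and linearly combine the denoising target with the
#' summed block: `target = -eps/sigma + V (F0 + eps/sigma)`. With a `NULL`
#' kernel (or `sigma2 = 0`) the forces-only targets `(R0, F0)` are returned.
#'
#' @param dataset A [fine_dataset()] (a single-frame dataset composes one
#'   frame).
#' @param mapping A [cg_mapping()].
#' @param t_atom An `atomistic_force_map`.
#' @param v_map A `noise_stage_map` (ignored in forces-only mode).
#' @param kernel A [noise_kernel()] or `NULL` for forces-only mode.
#' @param seed Optional seed; `NULL` draws from the current stream.
#' @param n_draws Noise draws per frame.
#' @return List with arrays `R`, `target` (`[m * n_draws, N, dim]`), plus
#'   `R0`, `F0`, `eps` and the frame index of each row.
#' @export
compose_targets <- function(dataset, mapping, t_atom, v_map = NULL,
                            kernel = NULL, seed = NULL, n_draws = 1) {
  R0 <- .map_frames(mapping$matrix, dataset$positions)
  F0 <- .map_frames(t_atom$matrix, dataset$forces)
  if (is.null(kernel) || kernel$sigma2 == 0) {
    return(list(R = R0, target = F0, R0 = R0, F0 = F0, eps = NULL,
                frame = seq_len(dim(R0)[1])))
  }
  stopifnot(!is.null(v_map))
  m <- dim(R0)[1]; N <- dim(R0)[2]; d <- dim(R0)[3]
  sig <- sqrt(kernel$sigma2)
  .maybe_seed(seed)
  eps <- array(rnorm(m * N * d * n_draws), dim = c(m * n_draws, N, d))
  idx <- rep(seq_len(m), times = n_draws)
  R <- R0[idx, , , drop = FALSE] + sig * eps
  Vh <- .map_frames(v_map$matrix, F0[idx, , , drop = FALSE] + eps / sig)
  target <- -eps / sig + Vh
  .assert_finite(target, "composed target")
  list(R = R, target = target, R0 = R0, F0 = F0, eps = eps, frame = idx)
}

#' Monte-Carlo residual report for a force-map pair
#'
#' Estimates the mean squared norm of the composed target,
#' `<E_kappa |target|^2>` (sum over sites and dimensions, mean over frames
#' and draws) — the quantity the staged maps are defined to minimize.
#'
#' @inheritParams compose_targets
#' @param n_noise_draws Draws per frame.
#' @return A `force_map_report` with `residual_msq`, `n_frames`,
#'   `n_noise_draws` and `seed`.
#' @export
residual_report <- function(dataset, mapping, t_atom, v_map = NULL,
                            kernel = NULL, n_noise_draws = 1, seed = 1) {
  m <- dim(dataset$positions)[1]
  if (m < 1) stop("empty dataset")
  ct <- compose_targets(dataset, mapping, t_atom, v_map, kernel,
                        seed = seed, n_draws = n_noise_draws)
  msq <- sum(ct$target^2) / dim(ct$target)[1]
  structure(list(residual_msq = msq, n_frames = m,
                 n_noise_draws = n_noise_draws, seed = seed),
            class = "force_map_report")
}

#' @export
print.force_map_report <- function(x, ...) {
  cat(sprintf("<force_map_report: residual <|Tf|^2> = %.6g (%d frames x %d draws)>\n",
              x$residual_msq, x$n_frames, x$n_noise_draws))
  invisible(x)
}
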