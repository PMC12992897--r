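# The CG map M, its probabilistic replacement (an isotropic Gaussian noise
# kernel), and the extended-system force assembly.
#
# The kernel density is kappa(R, r) ∝ exp(-|Mr - R|^2 / (2 sigma2)); its log
# gradients are the "noise forces" entering the extended-system force: the
# training target combines the atomistic force -grad u(r) with
# grad log kappa, all in thermal units.

#' Linear coarse-graining map
#'
#' @param matrix Coefficient matrix `M` (`N` CG sites by `n` fine particles),
#'   applied identically per spatial dimension.
#' @param sites Alternatively, an integer vector of fine-particle indices
#'   defining a slice map (one CG site copies one particle).
#' @param n_fine Number of fine particles (required with `sites`).
#' @param site_names Optional CG site labels.
#' @return A `cg_mapping` with an `is_slice` flag.
#' @export
#' @examples
#' cg_mapping(sites = c(1, 3), n_fine = 5)
cg_mapping <- function(matrix = NULL, sites = NULL, n_fine = NULL,
                       site_names = NULL) {
  if (is.null(matrix)) {
    stopifnot(!is.null(sites), !is.null(n_fine))
    matrix <- base::matrix(0, length(sites), n_fine)
    matrix[cbind(seq_along(sites), sites)] <- 1
  }
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1) stop("mapping must have at least one CG site")
  if (any(rowSums(abs(matrix)) == 0))
    stop("every mapping row must have at least one nonzero coefficient")
  is_slice <- all(apply(matrix, 1, function(row) {
    sum(row != 0) == 1 && sum(row) == 1
  }))
  structure(list(matrix = unname(matrix), site_names = site_names,
                 is_slice = is_slice),
            class = "cg_mapping")
}

#' @export
print.cg_mapping <- function(x, ...) {
  cat(sprintf("<cg_mapping: %d sites from %d particles%s>\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$is_slice) ", slice" else ""))
  invisible(x)
}

#' Apply a CG map to configurations
#'
#' @param mapping A [cg_mapping()].
#' @param r A configuration matrix `[n, dim]` or a frames array
#'   `[m, n, dim]`.
#' @return Mapped coordinates with the same frame structure.
#' @export
apply_map <- function(mapping, r) {
  M <- mapping$matrix
  if (length(dim(r)) == 3L) return(.map_frames(M, r))
  r <- as.matrix(r)
  if (nrow(r) != ncol(M)) stop("configuration size does not match mapping")
  M %*% r
}

#' Gaussian noise kernel
#'
#' @param sigma2 Noise level: the variance of the isotropic Gaussian, in
#'   squared coordinate units. `sigma2 = 0` denotes the degenerate kernel
#'   concentrated at `Mr` (forces-only mode). Values above 0.01 (in the
#'   paper-scale squared-angstrom convention) are known to degrade the
#'   learned PMF and trigger a warning.
#' @param warn Emit the high-noise warning (default `TRUE`); oracle studies
#'   that scan large noise levels deliberately may disable it.
#' @return A `noise_kernel`.
#' @export
noise_kernel <- function(sigma2, warn = TRUE) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (warn && sigma2 > 0.01)
    warning("noise levels above 0.01 squared coordinate units can be detrimental")
  structure(list(sigma2 = sigma2), class = "noise_kernel")
}

#' @export
print.noise_kernel <- function(x, ...) {
  cat(sprintf("<noise_kernel: sigma2 = %g>\n", x$sigma2))
  invisible(x)
}

#' Sample noised CG coordinates
#'
#' Applies the kernel: `R = R0 + sigma * eps` with `eps` standard normal per
#' coordinate. Both `R` and `eps` are returned so downstream training targets
#' can be formed without re-deriving the noise.
#'
#' @param kernel A [noise_kernel()].
#' @param R0 Mapped coordinates: matrix `[N, dim]` or array `[m, N, dim]`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (training draws fresh noise from a seeded stream).
#' @return List with `R` and `eps` of the same shape as `R0`.
#' @export
sample_noise <- function(kernel, R0, seed = NULL) {
  .maybe_seed(seed)
  if (kernel$sigma2 == 0) {
    eps <- R0; eps[] <- 0
    return(list(R = R0, eps = eps))
  }
  eps <- R0
  eps[] <- rnorm(length(R0))
  list(R = R0 + sqrt(kernel$sigma2) * eps, eps = eps)
}

#' Noise-force blocks of the Gaussian kernel
#'
#' Closed forms: `grad_R log kappa = (Mr - R) / sigma2` and
#' `grad_r log kappa = -M' (Mr - R) / sigma2`; the identity
#' `grad_r = -M' grad_R` holds exactly.
#'
#' @param kernel A [noise_kernel()] with `sigma2 > 0`.
#' @param mapping A [cg_mapping()].
#' @param r Fine configuration `[n, dim]`.
#' @param R Noised CG configuration `[N, dim]`.
#' @return List with `gradR_logk` and `gradr_logk`.
#' @export
noise_force_blocks <- function(kernel, mapping, r, R) {
  if (kernel$sigma2 == 0)
    stop("degenerate kernel (sigma2 = 0): use the forces-only mode instead")
  r <- as.matrix(r); R <- as.matrix(R)
  gR <- (mapping$matrix %*% r - R) / kernel$sigma2
  list(gradR_logk = gR, gradr_logk = -t(mapping$matrix) %*% gR)
}

#' Extended-system forces
#'
#' Assembles the force on the extended system `(R, r)`: the `r` block is the
#' atomistic MD force plus the kernel's log-gradient with respect to `r`; the
#' `R` block is the kernel's log-gradient with respect to `R`. Components are
#' stored separately.
#'
#' @param system_force Atomistic force `-grad u(r)`, matrix `[n, dim]`.
#' @param kernel,mapping,r,R As in [noise_force_blocks()].
#' @return An `extended_forces` list with `r_block`, `R_block`, `md_force`,
#'   `noise_force_r`, `noise_force_R`.
#' @export
extended_forces <- function(system_force, kernel, mapping, r, R) {
  .assert_finite(system_force, "system_force")
  .assert_finite(r, "r"); .assert_finite(R, "R")
  nb <- noise_force_blocks(kernel, mapping, r, R)
  structure(list(r_block = system_force + nb$gradr_logk,
                 R_block = nb$gradR_logk,
                 md_force = system_force,
                 noise_force_r = nb$gradr_logk,
                 noise_force_R = nb$gradR_logk),
            class = "extended_forces")
}

#' Read a mapping definition from a plain-text config
#'
#' The file is YAML with either `sites: [i, j, ...]` plus `n_fine`, or
#' `rows:` a list of `{indices, weights}` records.
#'
#' @param path Path to a YAML mapping file.
#' @return A [cg_mapping()].
#' @export
read_mapping <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sites)) {
    return(cg_mapping(sites = as.integer(y$sites), n_fine = as.integer(y$n_fine),
                      site_names = y$site_names))
  }
  stopifnot(!is.null(y$rows), !is.null(y$n_fine))
  M <- matrix(0, length(y$rows), as.integer(y$n_fine))
  for (i in seq_along(y$rows)) {
    M[i, as.integer(y$rows[[i]]$indices)] <- as.numeric(y$rows[[i]]$weights)
  }
  cg_mapping(matrix = M, site_names = y$site_names)
}
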