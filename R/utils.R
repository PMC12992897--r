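# Internal helpers shared across modules.

#' Derive a per-stage random seed from a global seed
#'
#' A single global seed fans out to per-stage seeds so that pipeline stages
#' are reproducible in isolation while remaining decoupled from each other.
#' The derivation is a fixed integer hash of the stage label folded into the
#' global seed, kept strictly below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"generate"`, `"train"`).
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1L, "generate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(as.numeric(utf8ToInt(stage)) * seq_along(utf8ToInt(stage)) * 131)
  out <- (abs(as.numeric(seed)) * 7919 + h) %% 2147483629
  as.integer(out + 1)
}

# Set the RNG seed only when one is supplied; otherwise use the current stream.
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  invisible(NULL)
}

# Moore-Penrose pseudoinverse via SVD (optionally ridge-damped).
.pinv_solve <- function(A, b, ridge = 0, tol = 1e-10, warn_singular = TRUE,
                        context = "linear system") {
  sv <- svd(A)
  d <- sv$d
  if (ridge > 0) {
    dinv <- d / (d^2 + ridge)
  } else {
    keep <- d > tol * max(d, 0)
    if (warn_singular && !all(keep)) {
      warning(sprintf("rank-deficient %s: returning minimum-norm solution",
                      context))
    }
    dinv <- ifelse(keep, 1 / d, 0)
  }
  sv$v %*% (dinv * crossprod(sv$u, b))
}

# Flatten an [n, d] coordinate matrix to a vector and back.
.flatten <- function(r) as.numeric(r)
.unflatten <- function(v, n, d) matrix(v, nrow = n, ncol = d)

# frames array helpers: positions are stored [n_frames, n_particles, dim]
.frame <- function(arr, i) {
  d <- dim(arr)
  matrix(arr[i, , ], nrow = d[2], ncol = d[3])
}

.n_frames <- function(arr) dim(arr)[1]

# Stack a list of n x d matrices into an [m, n, d] array.
.stack_frames <- function(lst) {
  n <- nrow(lst[[1]]); d <- ncol(lst[[1]])
  out <- array(0, dim = c(length(lst), n, d))
  for (i in seq_along(lst)) out[i, , ] <- lst[[i]]
  out
}

# Apply a matrix A (k x n) to every frame of an [m, n, d] array -> [m, k, d].
.map_frames <- function(A, arr) {
  m <- dim(arr)[1]; n <- dim(arr)[2]; d <- dim(arr)[3]
  stopifnot(ncol(A) == n)
  out <- array(0, dim = c(m, nrow(A), d))
  for (j in seq_len(d)) out[, , j] <- arr[, , j] %*% t(A)
  out
}

.assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(TRUE)
}

# md5 of a file, used for artifact provenance / determinism checks.
.file_hash <- function(path) unname(tools::md5sum(path))

# md5 hash of an arbitrary R object via a temporary serialization.
.object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2)
  close(con)
  .file_hash(tf)
}
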