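# CG potentials: prior energy terms plus a trainable component with analytic
# forces. The trainable energy doubles as the score model in noise-only mode
# (the predicted force is the learned score of the noised marginal).
#
# Two trainable forms are provided: a linear-in-parameters basis (convex
# training, exact closed-form fits, used for oracle checks) and a small
# one-hidden-layer MLP on the same descriptors (the non-convex path).
# Parameter gradients of the force-matching loss are computed analytically,
# including the mixed second derivative through the force.

# --- feature bases ---------------------------------------------------------

#' Feature basis specifications
#'
#' Descriptor families for trainable CG energies:
#' * `rbf_distance`: Gaussian radial basis functions of pairwise site
#'   distances (translation/rotation invariant).
#' * `rbf_projection`: Gaussian RBFs of a scalar linear projection `w . R`
#'   of the flattened coordinates (translation invariant iff the projection
#'   weights sum to zero per dimension).
#' * `poly_projection`: monomials of a scalar linear projection.
#' * `quadratic`: all monomials `R_a R_b` of the flattened coordinates — the
#'   explicitly non-invariant oracle mode used to recover quadratic PMFs.
#'
#' @param pairs Two-column matrix of site index pairs.
#' @param centers RBF centers; `width` their common width (> 0).
#' @param w Projection weight vector over flattened coordinates
#'   (length `N * dim`).
#' @param powers Integer exponents for the polynomial mode.
#' @param n_sites,dim Coordinate layout for the quadratic mode.
#' @return A `feature_spec`.
#' @name feature_specs
NULL

#' @rdname feature_specs
#' @export
feature_rbf_distance <- function(pairs, centers, width) {
  if (width <= 0) stop("RBF width (cutoff scale) must be > 0")
  structure(list(kind = "rbf_distance", pairs = as.matrix(pairs),
                 centers = centers, width = width,
                 n_features = nrow(as.matrix(pairs)) * length(centers)),
            class = "feature_spec")
}

#' @rdname feature_specs
#' @export
feature_rbf_projection <- function(w, centers, width) {
  if (width <= 0) stop("RBF width must be > 0")
  structure(list(kind = "rbf_projection", w = as.numeric(w),
                 centers = centers, width = width,
                 n_features = length(centers)),
            class = "feature_spec")
}

#' @rdname feature_specs
#' @export
feature_poly_projection <- function(w, powers = c(2, 4)) {
  structure(list(kind = "poly_projection", w = as.numeric(w),
                 powers = as.integer(powers), n_features = length(powers)),
            class = "feature_spec")
}

#' @rdname feature_specs
#' @export
feature_quadratic <- function(n_sites, dim = 1) {
  D <- n_sites * dim
  ij <- which(upper.tri(matrix(0, D, D), diag = TRUE), arr.ind = TRUE)
  structure(list(kind = "quadratic", n_sites = n_sites, dim = dim,
                 idx = ij, n_features = nrow(ij)),
            class = "feature_spec")
}

#' Evaluate a feature basis
#'
#' @param R CG configuration matrix `[N, dim]`.
#' @param spec A [feature_spec][feature_specs].
#' @return Numeric feature vector.
#' @export
feature_basis <- function(R, spec) {
  v <- .flatten(as.matrix(R))
  switch(spec$kind,
    quadratic = v[spec$idx[, 1]] * v[spec$idx[, 2]],
    poly_projection = sum(spec$w * v)^spec$powers,
    rbf_projection = {
      t0 <- sum(spec$w * v)
      exp(-(t0 - spec$centers)^2 / (2 * spec$width^2))
    },
    rbf_distance = {
      R <- as.matrix(R)
      out <- numeric(0)
      for (p in seq_len(nrow(spec$pairs))) {
        dv <- R[spec$pairs[p, 1], ] - R[spec$pairs[p, 2], ]
        dd <- sqrt(sum(dv^2))
        out <- c(out, exp(-(dd - spec$centers)^2 / (2 * spec$width^2)))
      }
      out
    }
  )
}

# Jacobian d(features)/d(flattened R): matrix [n_features, N*dim].
.feature_jacobian <- function(R, spec) {
  R <- as.matrix(R)
  v <- .flatten(R)
  D <- length(v)
  switch(spec$kind,
    quadratic = {
      J <- matrix(0, spec$n_features, D)
      for (f in seq_len(spec$n_features)) {
        a <- spec$idx[f, 1]; b <- spec$idx[f, 2]
        J[f, a] <- J[f, a] + v[b]
        J[f, b] <- J[f, b] + v[a]
      }
      J
    },
    poly_projection = {
      t0 <- sum(spec$w * v)
      outer(spec$powers * t0^(spec$powers - 1), spec$w)
    },
    rbf_projection = {
      t0 <- sum(spec$w * v)
      phi <- exp(-(t0 - spec$centers)^2 / (2 * spec$width^2))
      outer(phi * (-(t0 - spec$centers) / spec$width^2), spec$w)
    },
    rbf_distance = {
      d <- ncol(R)
      J <- matrix(0, spec$n_features, D)
      nc <- length(spec$centers)
      for (p in seq_len(nrow(spec$pairs))) {
        i <- spec$pairs[p, 1]; j <- spec$pairs[p, 2]
        dv <- R[i, ] - R[j, ]
        dd <- sqrt(sum(dv^2))
        unit <- if (dd > 0) dv / dd else rep(0, d)
        phi <- exp(-(dd - spec$centers)^2 / (2 * spec$width^2))
        dphi <- phi * (-(dd - spec$centers) / spec$width^2)
        for (k in seq_len(nc)) {
          row <- (p - 1) * nc + k
          # flattened index of site i, dim q is (q-1)*N + i
          N <- nrow(R)
          for (q in seq_len(d)) {
            J[row, (q - 1) * N + i] <- dphi[k] * unit[q]
            J[row, (q - 1) * N + j] <- -dphi[k] * unit[q]
          }
        }
      }
      J
    }
  )
}

# --- trainable energies ----------------------------------------------------

#' Trainable CG energy
#'
#' @param form `"linear"` (energy `theta . phi(R)`) or `"mlp"` (one hidden
#'   tanh layer on the features).
#' @param spec A [feature_spec][feature_specs].
#' @param params Optional parameter vector; defaults to zeros (linear) or a
#'   small seeded random initialization (mlp).
#' @param hidden Hidden width for the MLP.
#' @param seed Seed for the MLP initialization.
#' @return A `trainable_energy`.
#' @export
trainable_energy <- function(form = c("linear", "mlp"), spec, params = NULL,
                             hidden = 8, seed = 1) {
  form <- match.arg(form)
  P <- spec$n_features
  if (form == "linear") {
    if (is.null(params)) params <- numeric(P)
    stopifnot(length(params) == P)
    layout <- NULL
  } else {
    H <- hidden
    layout <- list(H = H, P = P,
                   W1 = seq_len(H * P),
                   b1 = H * P + seq_len(H),
                   w2 = H * P + H + seq_len(H),
                   b2 = H * P + 2 * H + 1L)
    if (is.null(params)) {
      .maybe_seed(seed)
      params <- c(rnorm(H * P, sd = 1 / sqrt(P)), numeric(H),
                  rnorm(H, sd = 1 / sqrt(H)), 0)
    }
    stopifnot(length(params) == H * P + 2 * H + 1)
  }
  structure(list(form = form, spec = spec, params = params,
                 layout = layout, hidden = hidden),
            class = "trainable_energy")
}

.mlp_unpack <- function(te) {
  l <- te$layout
  list(W1 = matrix(te$params[l$W1], l$H, l$P), b1 = te$params[l$b1],
       w2 = te$params[l$w2], b2 = te$params[l$b2])
}

.te_energy <- function(te, R) {
  phi <- feature_basis(R, te$spec)
  if (te$form == "linear") return(sum(te$params * phi))
  w <- .mlp_unpack(te)
  a <- tanh(as.numeric(w$W1 %*% phi) + w$b1)
  sum(w$w2 * a) + w$b2
}

# dU/dphi at a configuration (vector of length n_features).
.te_dU_dphi <- function(te, phi) {
  if (te$form == "linear") return(te$params)
  w <- .mlp_unpack(te)
  a <- tanh(as.numeric(w$W1 %*% phi) + w$b1)
  as.numeric(crossprod(w$W1, w$w2 * (1 - a^2)))
}

.te_force <- function(te, R) {
  phi <- feature_basis(R, te$spec)
  J <- .feature_jacobian(R, te$spec)
  f <- -as.numeric(crossprod(J, .te_dU_dphi(te, phi)))
  matrix(f, nrow = nrow(as.matrix(R)))
}

# Gradient of the per-sample squared force error wrt the trainable params.
# g_res is d(loss)/d(F_pred) flattened (same length as coords).
.te_force_param_grad <- function(te, R, g_res) {
  phi <- feature_basis(R, te$spec)
  J <- .feature_jacobian(R, te$spec)           # P x D
  q <- as.numeric(J %*% g_res)                 # P
  if (te$form == "linear") return(-q)
  w <- .mlp_unpack(te)
  z <- as.numeric(w$W1 %*% phi) + w$b1
  a <- tanh(z); s <- 1 - a^2
  p <- as.numeric(w$W1 %*% q)                  # H
  grad_w2 <- -s * p
  common <- 2 * (p * w$w2 * a * s)             # H
  grad_W1 <- -tcrossprod(w$w2 * s, q) + tcrossprod(common, phi)
  grad_b1 <- common
  c(as.numeric(grad_W1), grad_b1, grad_w2, 0)
}

# --- priors ----------------------------------------------------------------

#' Prior energy terms
#'
#' Harmonic bonds between CG site pairs plus an optional power-law repulsion
#' for non-bonded pairs, the usual physics baseline stabilizing machine-
#' learned CG potentials.
#'
#' @param bonds Data frame with columns `i`, `j`, `k` (stiffness >= 0) and
#'   `r0` (rest length).
#' @param repulsion Optional list with `prefactor`, `scale`, `exponent` and a
#'   two-column `pairs` matrix.
#' @return A `prior_terms`.
#' @export
prior_terms <- function(bonds = NULL, repulsion = NULL) {
  if (!is.null(bonds)) {
    stopifnot(all(c("i", "j", "k", "r0") %in% names(bonds)),
              all(bonds$k >= 0))
  }
  structure(list(bonds = bonds, repulsion = repulsion), class = "prior_terms")
}

.prior_energy <- function(pr, R) {
  if (is.null(pr)) return(0)
  R <- as.matrix(R)
  u <- 0
  if (!is.null(pr$bonds)) {
    for (b in seq_len(nrow(pr$bonds))) {
      dv <- R[pr$bonds$i[b], ] - R[pr$bonds$j[b], ]
      u <- u + 0.5 * pr$bonds$k[b] * (sqrt(sum(dv^2)) - pr$bonds$r0[b])^2
    }
  }
  if (!is.null(pr$repulsion)) {
    rp <- pr$repulsion
    for (p in seq_len(nrow(rp$pairs))) {
      dv <- R[rp$pairs[p, 1], ] - R[rp$pairs[p, 2], ]
      dd <- sqrt(sum(dv^2))
      if (dd < 1e-8) {
        warning("coincident sites in repulsive prior; capping distance")
        dd <- 1e-8
      }
      u <- u + rp$prefactor * (rp$scale / dd)^rp$exponent
    }
  }
  u
}

.prior_force <- function(pr, R) {
  R <- as.matrix(R)
  F <- matrix(0, nrow(R), ncol(R))
  if (is.null(pr)) return(F)
  if (!is.null(pr$bonds)) {
    for (b in seq_len(nrow(pr$bonds))) {
      i <- pr$bonds$i[b]; j <- pr$bonds$j[b]
      dv <- R[i, ] - R[j, ]
      dd <- sqrt(sum(dv^2))
      unit <- if (dd > 0) dv / dd else rep(0, ncol(R))
      g <- pr$bonds$k[b] * (dd - pr$bonds$r0[b]) * unit
      F[i, ] <- F[i, ] - g
      F[j, ] <- F[j, ] + g
    }
  }
  if (!is.null(pr$repulsion)) {
    rp <- pr$repulsion
    for (p in seq_len(nrow(rp$pairs))) {
      i <- rp$pairs[p, 1]; j <- rp$pairs[p, 2]
      dv <- R[i, ] - R[j, ]
      dd <- max(sqrt(sum(dv^2)), 1e-8)
      g <- -rp$prefactor * rp$exponent * rp$scale^rp$exponent /
        dd^(rp$exponent + 1) * (dv / dd)
      F[i, ] <- F[i, ] - g
      F[j, ] <- F[j, ] + g
    }
  }
  F
}

#' Fit harmonic bond priors by moment matching
#'
#' Bond stiffness `k = 1/var(d)` and rest length `r0 = mean(d)` from the
#' per-frame bond-length series. When a noise kernel is supplied the
#' statistics are computed on Gaussian-noised bond lengths (the kernel
#' variance enters the internal coordinate once), matching the prior
#' fitting used with noised training data.
#'
#' @param cg_positions Frames array `[m, N, dim]` (m >= 100).
#' @param pairs Two-column matrix of bonded site pairs.
#' @param kernel Optional [noise_kernel()].
#' @param seed Seed for the noising draws.
#' @return A [prior_terms()] with fitted bonds.
#' @export
fit_priors <- function(cg_positions, pairs, kernel = NULL, seed = 1) {
  m <- dim(cg_positions)[1]
  if (m < 100) stop("at least 100 frames are required to fit priors")
  pairs <- as.matrix(pairs)
  .maybe_seed(seed)
  bonds <- data.frame(i = integer(0), j = integer(0), k = numeric(0),
                      r0 = numeric(0))
  for (b in seq_len(nrow(pairs))) {
    i <- pairs[b, 1]; j <- pairs[b, 2]
    dv <- cg_positions[, i, , drop = FALSE] - cg_positions[, j, , drop = FALSE]
    d <- sqrt(apply(dv^2, 1, sum))
    if (!is.null(kernel) && kernel$sigma2 > 0)
      d <- d + sqrt(kernel$sigma2) * rnorm(m)
    v <- var(d)
    if (v < 1e-12) stop(sprintf("zero-variance bond %d-%d", i, j))
    bonds <- rbind(bonds, data.frame(i = i, j = j, k = 1 / v, r0 = mean(d)))
  }
  prior_terms(bonds = bonds)
}

# --- assembled potential ---------------------------------------------------

#' Assembled CG potential
#'
#' Total energy is the sum of the prior terms and the trainable component;
#' forces are the analytic negative gradient.
#'
#' @param priors A [prior_terms()] or `NULL`.
#' @param trainable A [trainable_energy()] or `NULL`.
#' @return A `cg_potential`.
#' @export
cg_potential <- function(priors = NULL, trainable = NULL) {
  structure(list(priors = priors, trainable = trainable),
            class = "cg_potential")
}

#' @export
print.cg_potential <- function(x, ...) {
  cat(sprintf("<cg_potential: %s%s>\n",
              if (is.null(x$trainable)) "no trainable part"
              else sprintf("%s trainable (%d params)", x$trainable$form,
                           length(x$trainable$params)),
              if (is.null(x$priors)) "" else " + priors"))
  invisible(x)
}

#' Energy and forces of a CG potential
#'
#' @param potential A [cg_potential()].
#' @param R CG configuration matrix `[N, dim]`.
#' @return `cg_energy`: scalar energy; `cg_forces`: force matrix `[N, dim]`.
#' @export
cg_energy <- function(potential, R) {
  R <- as.matrix(R)
  .assert_finite(R, "R")
  u <- .prior_energy(potential$priors, R)
  if (!is.null(potential$trainable)) u <- u + .te_energy(potential$trainable, R)
  u
}

#' @rdname cg_energy
#' @export
cg_forces <- function(potential, R) {
  R <- as.matrix(R)
  .assert_finite(R, "R")
  F <- .prior_force(potential$priors, R)
  if (!is.null(potential$trainable)) F <- F + .te_force(potential$trainable, R)
  F
}

#' Replace the trainable parameters of a potential
#'
#' @param potential A [cg_potential()].
#' @param params New parameter vector for the trainable part.
#' @return The updated potential.
#' @export
set_params <- function(potential, params) {
  stopifnot(!is.null(potential$trainable),
            length(params) == length(potential$trainable$params))
  potential$trainable$params <- params
  potential
}
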