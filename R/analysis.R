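# Collective variables, histogram free-energy surfaces, FES error metrics,
# TICA and native-contact analysis.
#
# FES convention: F = -log(normalized count) in k_B T, min-shifted to 0 over
# populated bins; unpopulated bins are masked. The FES error is the mean
# absolute free-energy difference over bins populated in both surfaces with
# reference value below a cutoff (default 9 k_B T), after re-shifting both
# surfaces on the compared region — a bounded metric that saturates when a
# basin vanishes from one surface.

#' Collective-variable specification
#'
#' @param kind One of `distance`, `radius_of_gyration`, `rmsd`,
#'   `fraction_native_contacts`, `linear_projection`.
#' @param pair Site index pair (`distance`).
#' @param reference Reference configuration (`rmsd`,
#'   `fraction_native_contacts`).
#' @param contacts Two-column matrix of native contact pairs.
#' @param beta Switching steepness of the soft contact function (default 50
#'   inverse length units).
#' @param lambda Native-distance tolerance factor (default 1.2).
#' @param w Projection weights over flattened coordinates
#'   (`linear_projection`).
#' @return A `cv_spec`.
#' @export
cv_spec <- function(kind = c("distance", "radius_of_gyration", "rmsd",
                             "fraction_native_contacts", "linear_projection"),
                    pair = NULL, reference = NULL, contacts = NULL,
                    beta = 50, lambda = 1.2, w = NULL) {
  kind <- match.arg(kind)
  if (kind == "distance" && is.null(pair)) stop("distance cv needs `pair`")
  if (kind == "rmsd" && is.null(reference)) stop("rmsd cv needs `reference`")
  if (kind == "fraction_native_contacts" &&
      (is.null(reference) || is.null(contacts)))
    stop("native-contact cv needs `reference` and `contacts`")
  if (kind == "linear_projection" && is.null(w))
    stop("linear_projection cv needs `w`")
  structure(list(kind = kind, pair = pair, reference = reference,
                 contacts = contacts, beta = beta, lambda = lambda, w = w),
            class = "cv_spec")
}

# Kabsch optimal superposition RMSD (any spatial dimension).
.rmsd_one <- function(X, Yref) {
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Yref, 2, colMeans(Yref))
  if (ncol(X) == 1) return(sqrt(mean((X - Y)^2)))
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(rep(1, ncol(X) - 1), d))
  Rot <- sv$v %*% S %*% t(sv$u)
  sqrt(mean(rowSums((X %*% t(Rot) - Y)^2)))
}

#' Compute a collective-variable series
#'
#' One value per frame. RMSD uses optimal rigid-body superposition; the
#' fraction of native contacts uses a soft logistic switching function over
#' the reference contact distances.
#'
#' @param traj A [cg_trajectory()], [fine_dataset()] or frames array.
#' @param spec A [cv_spec()].
#' @return Numeric vector of per-frame values.
#' @export
compute_cv <- function(traj, spec) {
  arr <- if (inherits(traj, "cg_trajectory")) traj$frames
         else if (inherits(traj, "fine_dataset")) traj$positions
         else traj
  m <- dim(arr)[1]
  if (spec$kind %in% c("rmsd", "fraction_native_contacts")) {
    ref <- as.matrix(spec$reference)
    if (nrow(ref) != dim(arr)[2])
      stop("reference size does not match trajectory sites")
  }
  vapply(seq_len(m), function(i) {
    R <- .frame(arr, i)
    switch(spec$kind,
      distance = sqrt(sum((R[spec$pair[1], ] - R[spec$pair[2], ])^2)),
      radius_of_gyration = {
        C <- sweep(R, 2, colMeans(R))
        sqrt(mean(rowSums(C^2)))
      },
      rmsd = .rmsd_one(R, as.matrix(spec$reference)),
      fraction_native_contacts = {
        ref <- as.matrix(spec$reference)
        q <- vapply(seq_len(nrow(spec$contacts)), function(p) {
          i1 <- spec$contacts[p, 1]; i2 <- spec$contacts[p, 2]
          dd <- sqrt(sum((R[i1, ] - R[i2, ])^2))
          d0 <- sqrt(sum((ref[i1, ] - ref[i2, ])^2))
          1 / (1 + exp(spec$beta * (dd - spec$lambda * d0)))
        }, 0)
        mean(q)
      },
      linear_projection = sum(spec$w * .flatten(R))
    )
  }, 0)
}

#' Free-energy-surface grid
#'
#' @param breaks Bin edges (vector for 1-D; list of two vectors for 2-D).
#' @param free_energy Free energies in k_B T over bin centers (vector or
#'   matrix); min over populated bins is shifted to 0.
#' @param counts Optional bin counts (same shape).
#' @return A `fes_grid` with bin centers (`mids`), a populated-bin `mask`,
#'   counts and free energies.
#' @export
fes_grid <- function(breaks, free_energy, counts = NULL) {
  mids <- if (is.list(breaks)) lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
          else (breaks[-1] + breaks[-length(breaks)]) / 2
  mask <- is.finite(free_energy)
  if (!any(mask)) stop("no populated bins")
  free_energy[mask] <- free_energy[mask] - min(free_energy[mask])
  structure(list(breaks = breaks, mids = mids, free_energy = free_energy,
                 counts = counts, mask = mask),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("<fes_grid: %s bins, %d populated, max %.3g kT>\n",
              paste(dim(as.matrix(x$free_energy)), collapse = " x "),
              sum(x$mask), max(x$free_energy[x$mask])))
  invisible(x)
}

#' Histogram free-energy surface
#'
#' `F = -log(normalized count)` over a 1-D or 2-D histogram, min-shifted to
#' 0; unpopulated bins are masked (infinite free energy).
#'
#' @param series Numeric vector (1-D) or two-column matrix (2-D) of cv
#'   values.
#' @param breaks Bin edges (vector, or list of two vectors for 2-D).
#' @param weights Optional per-frame weights.
#' @return A [fes_grid()].
#' @export
histogram_fes <- function(series, breaks, weights = NULL) {
  if (is.matrix(series) && ncol(series) == 2) {
    stopifnot(is.list(breaks))
    bx <- breaks[[1]]; by <- breaks[[2]]
    ix <- findInterval(series[, 1], bx, rightmost.closed = TRUE)
    iy <- findInterval(series[, 2], by, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix < length(bx) & iy >= 1 & iy < length(by)
    if (!any(ok)) stop("empty series (no frames inside the grid)")
    w <- if (is.null(weights)) rep(1, length(ix)) else weights
    cnt <- matrix(0, length(bx) - 1, length(by) - 1)
    for (i in which(ok)) cnt[ix[i], iy[i]] <- cnt[ix[i], iy[i]] + w[i]
  } else {
    series <- as.numeric(series)
    if (length(series) == 0) stop("empty series")
    ix <- findInterval(series, breaks, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix < length(breaks)
    if (!any(ok)) stop("empty series (no frames inside the grid)")
    w <- if (is.null(weights)) rep(1, length(ix)) else weights
    cnt <- numeric(length(breaks) - 1)
    for (i in which(ok)) cnt[ix[i]] <- cnt[ix[i]] + w[i]
  }
  p <- cnt / sum(cnt)
  fe <- -log(p)
  fe[!is.finite(fe)] <- Inf
  fes_grid(breaks, fe, counts = cnt)
}

#' FES error between two surfaces
#'
#' Mean absolute free-energy difference over bins populated in both surfaces
#' whose reference value lies below `cutoff_kT`; both surfaces are re-shifted
#' (mean-aligned) on the compared region before differencing, so the metric
#' is offset-invariant and symmetric.
#'
#' @param fes_model,fes_ref [fes_grid()]s on identical breaks (`fes_ref` is
#'   the reference for the cutoff).
#' @param cutoff_kT Reference free-energy cutoff (default 9).
#' @return Scalar mean absolute error in k_B T.
#' @export
fes_error <- function(fes_model, fes_ref, cutoff_kT = 9) {
  if (!isTRUE(all.equal(fes_model$breaks, fes_ref$breaks)))
    stop("surfaces must share identical binning")
  sel <- fes_model$mask & fes_ref$mask & (fes_ref$free_energy < cutoff_kT)
  if (!any(sel)) stop("no jointly populated bins below the cutoff")
  a <- fes_model$free_energy[sel]; b <- fes_ref$free_energy[sel]
  a <- a - mean(a); b <- b - mean(b)
  mean(abs(a - b))
}

#' FES of a pmf_oracle on a given binning
#'
#' @param oracle A [pmf_oracle()].
#' @param breaks Bin edges.
#' @return A [fes_grid()] with the oracle evaluated at bin centers.
#' @export
fes_from_oracle <- function(oracle, breaks) {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  fes_grid(breaks, pmf_eval(oracle, mids))
}

#' FES implied by a CG potential along a 1-D coordinate
#'
#' Evaluates the potential on configurations parametrized by the coordinate
#' through an embedding function (default: two sites in one dimension at
#' `-x/2` and `+x/2`, so the coordinate is their signed separation). Valid as
#' a free-energy surface when the potential depends on the coordinate alone.
#'
#' @param potential A [cg_potential()].
#' @param breaks Bin edges over the coordinate.
#' @param embed Function mapping a coordinate value to a configuration
#'   matrix.
#' @return A [fes_grid()].
#' @export
fes_from_potential <- function(potential, breaks,
                               embed = function(x) matrix(c(-x / 2, x / 2),
                                                          ncol = 1)) {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  fe <- vapply(mids, function(x) cg_energy(potential, embed(x)), 0)
  fes_grid(breaks, fe)
}

#' Time-lagged independent component analysis
#'
#' Solves the symmetrized time-lagged covariance generalized eigenproblem:
#' with head/tail blocks at lag `tau`, `C0` is the symmetrized instantaneous
#' covariance and `Ctau` the symmetrized lagged covariance; components are
#' eigenvectors of `C0^{-1/2} Ctau C0^{-1/2}` mapped back through the
#' whitening transform, ordered by eigenvalue. Eigenvalues outside `[-1, 1]`
#' are clipped with a warning; a singular instantaneous covariance is
#' regularized with a small documented ridge. Sign convention: the largest-
#' magnitude loading of each component is positive.
#'
#' @param series_list A matrix `[frames, features]` or list of such matrices
#'   (independent trajectories).
#' @param lag Lag time in frames (>= 1).
#' @param ridge Ridge added to `C0` if it is numerically singular
#'   (default 1e-10 relative).
#' @return List with `eigenvalues`, `components` (columns are projection
#'   vectors in input coordinates) and the `mean` removed.
#' @export
tica <- function(series_list, lag, ridge = 1e-10) {
  if (lag < 1) stop("lag must be >= 1")
  if (!is.list(series_list)) series_list <- list(series_list)
  series_list <- lapply(series_list, as.matrix)
  p <- ncol(series_list[[1]])
  tot <- Reduce(`+`, lapply(series_list, colSums))
  ntot <- sum(vapply(series_list, nrow, 0L))
  mu <- tot / ntot
  C0 <- matrix(0, p, p); Ct <- matrix(0, p, p); npairs <- 0
  for (X in series_list) {
    X <- sweep(X, 2, mu)
    T0 <- nrow(X)
    if (T0 <= lag) stop("each trajectory must be longer than the lag")
    H <- X[seq_len(T0 - lag), , drop = FALSE]
    L <- X[(lag + 1):T0, , drop = FALSE]
    C0 <- C0 + crossprod(H) + crossprod(L)
    Ct <- Ct + crossprod(H, L) + crossprod(L, H)
    npairs <- npairs + (T0 - lag)
  }
  C0 <- C0 / (2 * npairs); Ct <- Ct / (2 * npairs)
  e0 <- eigen(C0, symmetric = TRUE)
  if (min(e0$values) < ridge * max(e0$values)) {
    warning("singular instantaneous covariance; applying ridge regularization")
    e0$values <- e0$values + ridge * max(e0$values)
  }
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), p) %*% t(e0$vectors)
  Msym <- W %*% Ct %*% W
  Msym <- (Msym + t(Msym)) / 2
  es <- eigen(Msym, symmetric = TRUE)
  ev <- es$values
  if (any(ev > 1 + 1e-8) || any(ev < -1 - 1e-8))
    warning("TICA eigenvalues outside [-1, 1]; clipping")
  ev <- pmin(pmax(ev, -1), 1)
  comps <- W %*% es$vectors
  for (j in seq_len(ncol(comps))) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  list(eigenvalues = ev, components = comps, mean = mu)
}
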