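# Ground-truth potentials of mean force.
#
# Two independent routes to the same quantity: closed-form Gaussian algebra
# for harmonic networks, and deterministic numerical quadrature for
# low-dimensional systems. Their agreement is part of the test suite.

#' Potential-of-mean-force oracle
#'
#' @param cv_grid Strictly increasing grid over the coarse coordinate.
#' @param free_energy Free energies in thermal units; min-shifted to 0.
#' @param form One of `quadratic_closed_form`, `quadrature`,
#'   `reference_sampling`.
#' @param precision Optional quadratic-form precision matrix (closed form).
#' @return A `pmf_oracle`.
#' @export
pmf_oracle <- function(cv_grid = NULL, free_energy = NULL,
                       form = "quadrature", precision = NULL) {
  if (!is.null(cv_grid)) {
    stopifnot(all(diff(cv_grid) > 0), length(cv_grid) == length(free_energy))
    free_energy <- free_energy - min(free_energy)
  }
  structure(list(cv_grid = cv_grid, free_energy = free_energy,
                 form = form, precision = precision),
            class = "pmf_oracle")
}

#' @export
print.pmf_oracle <- function(x, ...) {
  cat(sprintf("<pmf_oracle: %s%s>\n", x$form,
              if (!is.null(x$cv_grid)) sprintf(", %d grid points",
                                               length(x$cv_grid)) else ""))
  invisible(x)
}

#' Closed-form PMF of a (noised) Gaussian network marginal
#'
#' For `u(r) = 1/2 r'Kr` and the noised coarse variate `R = Mr + sigma eps`,
#' the marginal of `R` is Gaussian with covariance `M K^-1 M' + sigma2 I` per
#' spatial dimension; the PMF is the quadratic form with the inverse of that
#' matrix as precision.
#'
#' @param system A `gaussian_network` [fine_system][make_gaussian_network()].
#' @param mapping A [cg_mapping()].
#' @param sigma2 Noise level (variance, >= 0).
#' @param grid Optional grid for a single CG coordinate; when the mapping has
#'   one site the quadratic free energy is tabulated on it.
#' @return A `pmf_oracle` with `form = "quadratic_closed_form"` and the
#'   precision populated.
#' @export
gaussian_oracles <- function(system, mapping, sigma2 = 0, grid = NULL) {
  if (system$kind != "gaussian_network")
    stop("gaussian_oracles requires a gaussian_network system")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  M <- mapping$matrix
  K <- system$params$K
  S <- M %*% solve(K, t(M)) + sigma2 * diag(nrow(M))
  if (rcond(S) < 1e-12)
    stop("singular noised marginal covariance M K^-1 M' + sigma2 I")
  P <- solve(S)
  cv_grid <- NULL; fe <- NULL
  if (nrow(M) == 1) {
    if (is.null(grid)) {
      sdv <- sqrt(S[1, 1])
      grid <- seq(-4 * sdv, 4 * sdv, length.out = 101)
    }
    cv_grid <- grid
    fe <- 0.5 * P[1, 1] * grid^2
  }
  pmf_oracle(cv_grid, fe, form = "quadratic_closed_form", precision = P)
}

#' PMF by deterministic quadrature
#'
#' Integrates the Boltzmann density over all fine coordinates orthogonal to
#' a linear collective variable. For Gaussian networks the integration is a
#' tensor-product trapezoid rule in an orthonormal complement basis (up to 3
#' integrated dimensions); for the double-well chain the bath marginal is
#' carried out analytically (it is independent of the bond displacement), so
#' the PMF over the signed displacement is the bare double-well term; for the
#' uniform box the PMF is identically zero. A positive `sigma2` additionally
#' convolves the marginal density with the Gaussian noise the kernel adds to
#' the coarse coordinate.
#'
#' @param system A `fine_system`.
#' @param cv For `gaussian_network`: a weight vector over particles (dim-1
#'   systems) defining `x = w'r`; for `double_well_chain`: the string
#'   `"bond_displacement"`; for `uniform_box`: any weight vector.
#' @param grid Strictly increasing grid of cv values.
#' @param sigma2 Optional noise variance added to the coarse coordinate
#'   (for the chain, the displacement of two independently noised endpoints
#'   carries `2 sigma2`).
#' @param n_quad Points per integrated dimension (gaussian path).
#' @return A `pmf_oracle` with `form = "quadrature"`.
#' @export
quadrature_pmf <- function(system, cv, grid, sigma2 = 0, n_quad = 121) {
  stopifnot(all(diff(grid) > 0))
  fe <- switch(system$kind,
    gaussian_network = .quadrature_gaussian(system, cv, grid, sigma2, n_quad),
    double_well_chain = .quadrature_chain(system, cv, grid, sigma2),
    uniform_box = rep(0, length(grid)),
    stop("unsupported system kind for quadrature")
  )
  pmf_oracle(grid, fe, form = "quadrature")
}

.quadrature_gaussian <- function(system, w, grid, sigma2, n_quad) {
  if (system$dim != 1)
    stop("quadrature over gaussian networks is implemented for dim-1 systems")
  n <- system$n_particles
  w <- as.numeric(w)
  stopifnot(length(w) == n)
  if (n - 1 > 3)
    stop("at most 3 integrated dimensions are supported; use gaussian_oracles")
  # Orthonormal basis with first column along the cv direction.
  nw <- sqrt(sum(w^2))
  Q <- qr.Q(qr(cbind(w / nw, diag(n)[, -which.max(abs(w)), drop = FALSE])))
  if (sum(Q[, 1] * w) < 0) Q[, 1] <- -Q[, 1]
  A <- t(Q) %*% system$params$K %*% Q          # u = 1/2 s'As, cv = nw * s1
  if (n == 1) {
    log_marginal <- function(xs) -0.5 * A[1, 1] * (xs / nw)^2
  } else {
    Arr <- A[-1, -1, drop = FALSE]
    a1r <- A[1, -1]
    # integration bounds from the marginal spread of the complement coords
    Sd <- sqrt(diag(solve(Arr)))
    axes <- lapply(seq_len(n - 1), function(j)
      seq(-7 * Sd[j], 7 * Sd[j], length.out = n_quad))
    pts <- as.matrix(expand.grid(axes))
    wts <- Reduce(outer, lapply(axes, .trap_weights))
    base_q <- 0.5 * rowSums((pts %*% Arr) * pts)
    cross <- pts %*% a1r
    log_marginal <- function(xs) vapply(xs, function(x) {
      s1 <- x / nw
      log(sum(as.numeric(wts) * exp(-(0.5 * A[1, 1] * s1^2 + s1 * cross + base_q))))
    }, 0)
  }
  dens <- if (sigma2 > 0) .convolve_grid(grid, log_marginal, sigma2)
          else {
    logp <- log_marginal(grid)
    exp(logp - max(logp))
  }
  fe <- -log(dens)
  fe - min(fe)
}

.trap_weights <- function(x) {
  h <- diff(x)
  c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
}

# Discrete convolution of a density with N(0, s2): the source density is
# re-evaluated on a grid padded by 6 sd so edge bins receive their full mass.
.convolve_grid <- function(grid, log_dens_fn, s2) {
  h <- min(diff(grid))
  pad <- seq(h, 6 * sqrt(s2) + h, by = h)
  xg <- c(min(grid) - rev(pad), grid, max(grid) + pad)
  ld <- log_dens_fn(xg)
  dens <- exp(ld - max(ld))
  Kmat <- outer(grid, xg, function(a, b) exp(-(a - b)^2 / (2 * s2)))
  out <- as.numeric(Kmat %*% (dens * .trap_weights(xg)))
  out / max(out)
}

.quadrature_chain <- function(system, cv, grid, sigma2) {
  if (!identical(cv, "bond_displacement"))
    stop("double_well_chain quadrature supports cv = 'bond_displacement'")
  p <- system$params
  log_marginal <- function(xs) -p$a * (xs^2 - p$d0^2)^2
  # bath Gaussian integral is d-independent, so it cancels in the PMF
  dens <- if (sigma2 > 0) .convolve_grid(grid, log_marginal, 2 * sigma2)
          else exp(log_marginal(grid) - max(log_marginal(grid)))
  fe <- -log(dens)
  fe - min(fe)
}

#' Evaluate a pmf_oracle on a grid
#'
#' Quadratic-form oracles are evaluated exactly; tabulated oracles by linear
#' interpolation.
#'
#' @param oracle A [pmf_oracle()].
#' @param grid Points at which to evaluate (single CG coordinate).
#' @return Free energies in thermal units, min-shifted on the grid.
#' @export
pmf_eval <- function(oracle, grid) {
  fe <- if (oracle$form == "quadratic_closed_form" && !is.null(oracle$precision) &&
            nrow(oracle$precision) == 1) {
    0.5 * oracle$precision[1, 1] * grid^2
  } else if (!is.null(oracle$cv_grid)) {
    stats::approx(oracle$cv_grid, oracle$free_energy, xout = grid, rule = 2)$y
  } else {
    stop("oracle has no tabulated grid and is not a scalar quadratic form")
  }
  fe - min(fe)
}

#' Equilibrium probability of a half-line basin from a tabulated PMF
#'
#' Integrates `exp(-F)` over the grid on both sides of a dividing value,
#' giving the Boltzmann weight of the `cv < divide` basin.
#'
#' @param oracle A [pmf_oracle()] with a tabulated grid.
#' @param divide Dividing surface along the cv.
#' @return Probability of the basin left of `divide`.
#' @export
basin_probability <- function(oracle, divide = 0) {
  g <- oracle$cv_grid
  w <- .trap_weights(g)
  p <- exp(-oracle$free_energy) * w
  # a grid point exactly on the divide contributes half to each basin
  (sum(p[g < divide]) + 0.5 * sum(p[g == divide])) / sum(p)
}
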