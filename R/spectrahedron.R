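# Geometry of the admissible set of noise correlations: correlation matrices
# (unit diagonal, entries in [-1,1]) that are positive semidefinite.  With the
# diagonal fixed this is a bounded convex spectrahedron in R^{N(N-1)/2}.
# Scaling by the positive diagonal of noise standard deviations preserves
# definiteness, so admissibility of C^n is equivalent to admissibility of the
# correlation matrix itself; `noise_vars` arguments are accepted for interface
# symmetry but do not affect membership.

#' Classify a correlation point (admissible / boundary)
#'
#' Eigenvalue-based membership test for the spectrahedron of correlation
#' matrices with unit diagonal.  A point is admissible when the smallest
#' eigenvalue is `>= -tol * lambda_max` and on the boundary when additionally
#' the smallest eigenvalue is `<= tol * lambda_max`.
#'
#' @param corr pair vector of correlations in `[-1, 1]` (or a correlation
#'   matrix).
#' @param noise_vars optional noise variances (membership is unaffected;
#'   accepted for interface symmetry).
#' @param tol relative boundary tolerance.
#' @return object of class `correlation_point`: list with `corr` (pair
#'   vector), `min_eig`, `admissible`, `on_boundary`.
#' @export
classify_corr <- function(corr, noise_vars = NULL, tol = .boundary_tol) {
  R <- if (is.matrix(corr)) .sym(corr) else pairvec_to_corrmat(as.numeric(corr))
  if (any(abs(corrmat_to_pairvec(R)) > 1 + 1e-12)) {
    stop("correlations must lie in [-1, 1]")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev))
  admissible <- min(ev) >= -tol * scale
  structure(
    list(corr = corrmat_to_pairvec(R),
         min_eig = min(ev),
         admissible = admissible,
         on_boundary = admissible && min(ev) <= tol * scale),
    class = "correlation_point"
  )
}

#' @export
print.correlation_point <- function(x, ...) {
  cat("<correlation_point> N =", n_from_pairs(length(x$corr)),
      " min_eig =", format(x$min_eig, digits = 4),
      if (x$admissible) if (x$on_boundary) "(boundary)" else "(interior)"
      else "(inadmissible)", "\n")
  invisible(x)
}

#' Maximal admissible step along a direction
#'
#' Largest `t >= 0` such that `corr0 + t * direction` remains an admissible
#' correlation point.  When the starting matrix is positive definite this is
#' solved exactly through the symmetric eigenproblem of
#' \eqn{R_0^{-1/2} B R_0^{-1/2}} (with `B` the zero-diagonal direction
#' matrix): \eqn{t_{max} = -1/\lambda_{min}}.  From a boundary start the step
#' is found by bisection.  Any nonzero zero-diagonal direction has a negative
#' eigenvalue, so the ray always exits the (bounded) set; a zero direction is
#' an error.
#'
#' @param corr0 admissible starting pair vector.
#' @param direction pair vector; need not be normalized.
#' @param noise_vars optional, see [classify_corr()].
#' @return scalar `t_max >= 0`.
#' @export
max_step <- function(corr0, direction, noise_vars = NULL) {
  corr0 <- as.numeric(corr0); direction <- as.numeric(direction)
  if (length(direction) != length(corr0)) stop("dimension mismatch")
  if (all(direction == 0)) stop("direction must be nonzero")
  n <- n_from_pairs(length(corr0))
  R0 <- pairvec_to_corrmat(corr0, n)
  B <- pairvec_to_corrmat(direction, n) - diag(1, n)
  cp0 <- classify_corr(corr0)
  if (!cp0$admissible) stop("corr0 must be admissible")
  ev0 <- eigen(R0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) > 1e-10 * max(ev0)) {
    e <- eigen(R0, symmetric = TRUE)
    half_inv <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
    W <- .sym(half_inv %*% B %*% half_inv)
    lmin <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin >= -1e-14) stop("direction does not exit the spectrahedron; ",
                             "inconsistent with a bounded admissible set")
    return(-1 / lmin)
  }
  # boundary start: bracket then bisect on the exact eigenvalue sign
  # (tolerance-free, so the result matches the closed form's precision);
  # allow for the start itself sitting a hair below zero
  floor0 <- min(0, min(ev0)) - 1e-13
  adm <- function(t) {
    v <- corr0 + t * direction
    if (any(abs(v) > 1 + 1e-12)) return(FALSE)
    R <- pairvec_to_corrmat(v, n)
    min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= floor0
  }
  hi <- 1
  while (adm(hi) && hi < 2 / max(abs(direction))) hi <- hi * 2
  if (adm(hi)) return(hi)
  lo <- 0
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    if (adm(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Random admissible correlation point of controlled rank
#'
#' Gram matrix of `N` random unit vectors in dimension `d`: `d < N` yields
#' boundary (rank-deficient) points, `d = N` generically interior points.
#' Deterministic under a fixed seed.
#'
#' @param n number of neurons.
#' @param d rank parameter, `1 <= d <= n`.
#' @param seed optional integer seed (uses the current RNG stream if `NULL`).
#' @return a `correlation_point` (see [classify_corr()]).
#' @export
random_admissible <- function(n, d = n, seed = NULL) {
  if (d < 1 || d > n) stop("rank d must satisfy 1 <= d <= n")
  if (!is.null(seed)) set.seed(seed)
  V <- matrix(stats::rnorm(d * n), nrow = d)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  R <- .sym(crossprod(V))
  diag(R) <- 1
  classify_corr(pmin(1, pmax(-1, corrmat_to_pairvec(R))))
}

#' Project a pair vector onto the spectrahedron
#'
#' Nearest-correlation-style projection: Dykstra's alternating projections
#' between the positive-semidefinite cone (eigenvalue clipping, optionally
#' with a strictly positive floor `pd_floor`) and the unit-diagonal affine
#' set.  Used as the feasibility map inside the optimizer.
#'
#' @param corr pair vector (any values).
#' @param pd_floor minimum eigenvalue to enforce (0 for plain PSD).
#' @param maxit,tol iteration controls.
#' @return admissible pair vector.
#' @export
project_spectrahedron <- function(corr, pd_floor = 0, maxit = 60, tol = 1e-11) {
  n <- n_from_pairs(length(corr))
  X <- pairvec_to_corrmat(pmin(2, pmax(-2, as.numeric(corr))), n)
  ev0 <- eigen(.sym(X), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) >= pd_floor) return(pmin(1, pmax(-1, corrmat_to_pairvec(X))))
  dS <- matrix(0, n, n)
  for (it in seq_len(maxit)) {
    Rk <- X - dS
    e <- eigen(.sym(Rk), symmetric = TRUE)
    Xp <- e$vectors %*% (pmax(e$values, pd_floor) * t(e$vectors))
    dS <- Xp - Rk
    X <- Xp
    diag(X) <- 1
    ev <- eigen(.sym(X), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= pd_floor - tol) break
  }
  out <- pmin(1, pmax(-1, corrmat_to_pairvec(.sym(X))))
  # final safeguard: shrink toward independence if still slightly indefinite
  cp <- classify_corr(out)
  if (cp$min_eig < pd_floor) {
    lmin <- cp$min_eig
    a <- (pd_floor - lmin + 1e-14) / (1 - lmin + 1e-14)
    out <- (1 - a) * out
  }
  out
}
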