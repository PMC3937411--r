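#' Linear Fisher information
#'
#' Accuracy of a locally linear unbiased stimulus decoder:
#' \deqn{I_F = f'^\top (C^n)^{-1} f'}
#' where \eqn{f'} is the `N x K` sensitivity matrix and \eqn{C^n} the noise
#' covariance.  For a `K`-dimensional stimulus the result is a `K x K` matrix;
#' the scalar summary is its trace.  \eqn{C^n} must be positive definite for
#' the information to be finite.
#'
#' @param stats a [population_stats()] object (needs `sensitivities`).
#' @param noise a `noise_cov` object, a pair vector of correlations, or `NULL`
#'   for independent noise.
#' @return list with `matrix` (`K x K`) and `value` (its trace).
#' @export
linear_fisher <- function(stats, noise = NULL) {
  fp <- .need(stats, "sensitivities")
  noise <- .as_noise(stats, noise)
  M <- .pd_solve(noise$cov, fp, what = "noise covariance")
  mat <- .sym(crossprod(fp, M))
  list(matrix = mat, value = sum(diag(mat)))
}

#' Optimal linear estimator readout weights
#'
#' The mean-square-optimal linear readout of the stimulus from responses,
#' \deqn{A = (C^n + C^\mu)^{-1} L,}
#' an `N x K` matrix.  With `C^n = 0` this is the noise-free readout
#' \eqn{(C^\mu)^{-1} L} that also characterizes noise-canceling correlations.
#'
#' @inheritParams linear_fisher
#' @param zero_noise if `TRUE`, use `C^n = 0` (noise-free readout).
#' @return `N x K` matrix of readout weights.
#' @export
ole_solution <- function(stats, noise = NULL, zero_noise = FALSE) {
  L <- .need(stats, "cross_cov")
  Cmu <- .need(stats, "mean_resp_cov")
  Ctot <- if (zero_noise) Cmu else Cmu + .as_noise(stats, noise)$cov
  .pd_solve(Ctot, L, what = "total covariance (C^n + C^mu)")
}

#' Optimal linear estimator information
#'
#' The quantity subtracted from the stimulus variance to give the OLE's mean
#' squared error:
#' \deqn{I_{OLE} = L^\top (C^n + C^\mu)^{-1} L,}
#' a `K x K` matrix with trace as the scalar summary.  Larger values mean a
#' more accurate linear readout.
#'
#' @inheritParams ole_solution
#' @return list with `matrix` (`K x K`) and `value` (its trace).
#' @export
ole_info <- function(stats, noise = NULL, zero_noise = FALSE) {
  L <- .need(stats, "cross_cov")
  A <- ole_solution(stats, noise, zero_noise = zero_noise)
  mat <- .sym(crossprod(L, A))
  list(matrix = mat, value = sum(diag(mat)))
}

#' Mean squared error of the optimal linear estimator
#'
#' `trace(C^s) - trace(I_OLE)`; nonnegative whenever the supplied statistics
#' are realizable by an actual joint distribution of stimulus and response.
#'
#' @inheritParams ole_solution
#' @return scalar mean squared error.
#' @export
ole_mse <- function(stats, noise = NULL, zero_noise = FALSE) {
  Cs <- .need(stats, "stim_cov")
  sum(diag(Cs)) - ole_info(stats, noise, zero_noise = zero_noise)$value
}

#' Gaussian mutual information between stimulus and response
#'
#' For jointly Gaussian stimulus and response,
#' \deqn{I_{mut} = \tfrac12\,[\log\det(C^n + C^\mu) - \log\det C^n]}
#' in nats.  Joint Gaussianity imposes the consistency constraint
#' \eqn{C^\mu = L (C^s)^{-1} L^\top}, checked up to `consistency_tol`
#' (relative, spectral norm); violation is an error.  A singular but
#' positive-semidefinite `C^n` yields `+Inf` with a warning (the boundary
#' case); an indefinite `C^n` is an error.
#'
#' @inheritParams linear_fisher
#' @param consistency_tol relative tolerance for the joint-Gaussian
#'   consistency check.
#' @return scalar mutual information in nats (possibly `Inf`).
#' @export
mutual_info_gaussian <- function(stats, noise = NULL, consistency_tol = 1e-6) {
  L <- .need(stats, "cross_cov")
  Cmu <- .need(stats, "mean_resp_cov")
  Cs <- .need(stats, "stim_cov")
  implied <- L %*% .pd_solve(Cs, t(L), what = "stimulus covariance")
  dev <- norm(Cmu - implied, "2") / max(norm(implied, "2"), norm(Cmu, "2"), 1e-300)
  if (dev > consistency_tol) {
    stop("inconsistent joint covariance: C^mu differs from L (C^s)^-1 L^T ",
         "by relative ", format(dev, digits = 3), call. = FALSE)
  }
  Cn <- .as_noise(stats, noise)$cov
  ev <- eigen(.sym(Cn), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-300)
  if (min(ev) < -.psd_tol * scale) {
    stop("noise covariance is indefinite; mutual information undefined",
         call. = FALSE)
  }
  if (min(ev) <= .sing_tol * scale) {
    warning("noise covariance is singular; mutual information is infinite ",
            "(min eigenvalue ", format(min(ev), digits = 3), ")")
    return(Inf)
  }
  0.5 * (.pd_logdet(Cn + Cmu, "total covariance") - sum(log(ev)))
}

#' Evaluate one of the three information measures as a scalar
#'
#' Thin dispatcher used by the optimizer, curves and tests: the trace of
#' [linear_fisher()] or [ole_info()], or [mutual_info_gaussian()].
#'
#' @inheritParams linear_fisher
#' @param measure `"fisher"`, `"ole"` or `"mutual"`.
#' @return scalar information value.
#' @export
info_eval <- function(stats, measure = c("fisher", "ole", "mutual"),
                      noise = NULL) {
  measure <- match.arg(measure)
  switch(measure,
         fisher = linear_fisher(stats, noise)$value,
         ole = ole_info(stats, noise)$value,
         mutual = mutual_info_gaussian(stats, noise))
}

# Per-neuron sensitivity vectors used to define signal correlations.
# fisher: the rows of f' themselves.
# ole:    the rows of (D + C^mu)^{-1} L  (D = diag of noise variances) --
#         the readout weights at independent noise.
# mutual: the rows of D^{-1} L S^{-1/2} with S = C^s + L^T D^{-1} L, so that
#         the pairwise inner products reproduce (minus) the off-diagonal of
#         (D + C^mu)^{-1} under the joint-Gaussian consistency constraint.
# These choices make the gradient identity G = -w o xi hold exactly (see
# rescaling_weights), which is the defining property.
.sensitivity_vectors <- function(stats, measure) {
  D <- diag(stats$noise_vars, stats$n_neurons)
  switch(measure,
    fisher = .need(stats, "sensitivities"),
    ole = {
      L <- .need(stats, "cross_cov")
      Cmu <- .need(stats, "mean_resp_cov")
      .pd_solve(D + Cmu, L, what = "independent-noise total covariance")
    },
    mutual = {
      L <- .need(stats, "cross_cov")
      Cs <- .need(stats, "stim_cov")
      U <- L / stats$noise_vars              # rows of D^{-1} L
      S <- .sym(Cs + crossprod(L, U))
      es <- eigen(S, symmetric = TRUE)
      if (min(es$values) <= 0) stop("C^s + L^T D^-1 L must be positive definite")
      Sinvhalf <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
      U %*% Sinvhalf
    },
    stop("unknown measure"))
}

#' Signal correlations
#'
#' The similarity of two neurons' stimulus tuning, defined via normalized
#' per-neuron sensitivity vectors \eqn{v_i}:
#' \deqn{\xi_{ij} = \langle v_i, v_j\rangle / (\|v_i\|\,\|v_j\|).}
#' For the Fisher measure \eqn{v_i} is the i-th row of \eqn{f'} (for a scalar
#' stimulus \eqn{\xi_{ij}} reduces to the sign of \eqn{f'_i f'_j}).  For the
#' OLE and mutual-information measures the analogous vectors are the rows of
#' \eqn{(D + C^\mu)^{-1} L} and of \eqn{D^{-1} L (C^s + L^\top D^{-1}
#' L)^{-1/2}} respectively, with `D` the diagonal matrix of noise variances.
#' Pairs involving a zero-norm sensitivity vector are undefined and returned
#' as `NA` with the affected pairs listed in the `undefined_pairs` attribute
#' (never silently zero).
#'
#' @inheritParams info_eval
#' @return pair vector of correlations in `[-1, 1]` (entries `NA` where
#'   undefined), with attribute `undefined_pairs`.
#' @export
signal_correlations <- function(stats, measure = c("fisher", "ole", "mutual")) {
  measure <- match.arg(measure)
  V <- .sensitivity_vectors(stats, measure)
  nrm <- sqrt(rowSums(V^2))
  idx <- pair_index(stats$n_neurons)
  ip <- tcrossprod(V)
  xi <- ip[idx] / (nrm[idx[, 1]] * nrm[idx[, 2]])
  xi <- pmin(1, pmax(-1, xi))
  bad <- which(nrm[idx[, 1]] == 0 | nrm[idx[, 2]] == 0)
  if (length(bad)) {
    xi[bad] <- NA_real_
    warning(length(bad), " pair(s) have a zero-norm sensitivity vector; ",
            "signal correlation undefined there")
  }
  structure(xi, undefined_pairs = bad)
}

#' Gradient of an information measure with respect to noise correlations
#'
#' Derivative of the scalar measure with respect to the pairwise correlation
#' coefficients \eqn{\rho_{ij}} at a given correlation point (default: the
#' independent-noise point \eqn{\rho = 0}).  Closed forms used, with
#' \eqn{\sigma_i = } noise standard deviations and `M` the relevant solve:
#' \itemize{
#'   \item Fisher: \eqn{-2\sigma_i\sigma_j \langle M_i, M_j\rangle},
#'     \eqn{M = (C^n)^{-1} f'};
#'   \item OLE: \eqn{-2\sigma_i\sigma_j \langle A_i, A_j\rangle},
#'     \eqn{A = (C^n + C^\mu)^{-1} L};
#'   \item mutual: \eqn{\sigma_i\sigma_j\,[(C^n + C^\mu)^{-1}_{ij} -
#'     (C^n)^{-1}_{ij}]}.
#' }
#' At independence the gradient has entrywise sign opposite to the signal
#' correlations (the sign rule), and points along the locally steepest
#' information-increasing direction.
#'
#' @inheritParams info_eval
#' @param corr pair vector of the correlation point at which to evaluate
#'   (default zeros = independent noise).
#' @return pair vector of partial derivatives.
#' @export
info_gradient <- function(stats, measure = c("fisher", "ole", "mutual"),
                          corr = NULL) {
  measure <- match.arg(measure)
  n <- stats$n_neurons
  if (is.null(corr)) corr <- rep(0, n * (n - 1) / 2)
  noise <- .as_noise(stats, corr)
  s <- sqrt(stats$noise_vars)
  idx <- pair_index(n)
  ss <- s[idx[, 1]] * s[idx[, 2]]
  if (measure == "fisher") {
    fp <- .need(stats, "sensitivities")
    M <- .pd_solve(noise$cov, fp, what = "noise covariance")
    ip <- tcrossprod(M)
    return(-2 * ss * ip[idx])
  }
  if (measure == "ole") {
    L <- .need(stats, "cross_cov")
    Cmu <- .need(stats, "mean_resp_cov")
    A <- .pd_solve(noise$cov + Cmu, L, what = "total covariance")
    ip <- tcrossprod(A)
    return(-2 * ss * ip[idx])
  }
  # mutual: needs consistency like mutual_info_gaussian
  L <- .need(stats, "cross_cov")
  Cmu <- .need(stats, "mean_resp_cov")
  Cs <- .need(stats, "stim_cov")
  implied <- L %*% .pd_solve(Cs, t(L), what = "stimulus covariance")
  dev <- norm(Cmu - implied, "2") / max(norm(implied, "2"), norm(Cmu, "2"), 1e-300)
  if (dev > 1e-6) {
    stop("inconsistent joint covariance: C^mu differs from L (C^s)^-1 L^T",
         call. = FALSE)
  }
  Ctot_inv <- .pd_solve(noise$cov + Cmu, diag(n), what = "total covariance")
  Cn_inv <- .pd_solve(noise$cov, diag(n), what = "noise covariance")
  ss * (Ctot_inv[idx] - Cn_inv[idx])
}

#' Noise-free information bound for the OLE
#'
#' The OLE information attained with deterministic (noise-free) responses,
#' \eqn{\mathrm{tr}(L^\top (C^\mu)^{-1} L)}.  This upper-bounds the OLE
#' information for every admissible noise covariance, with equality exactly
#' for noise-canceling covariances (`C^n A = 0`).
#'
#' @inheritParams info_eval
#' @return scalar bound.
#' @export
noise_free_bound <- function(stats) {
  ole_info(stats, zero_noise = TRUE)$value
}

#' Euclidean strength of a correlation pattern
#'
#' The list of all pairwise correlations is a single point in
#' \eqn{R^{N(N-1)/2}}; its Euclidean 2-norm is the "strength of correlations".
#'
#' @param corr pair vector (or correlation matrix).
#' @return scalar norm.
#' @export
correlation_strength <- function(corr) {
  v <- if (is.matrix(corr)) corrmat_to_pairvec(corr) else as.numeric(corr)
  sqrt(sum(v^2))
}

#' Rescaling weights linking signal correlations to the information gradient
#'
#' Positive per-pair weights \eqn{w_{ij}} such that the gradient of the
#' measure at independent noise satisfies \eqn{G = -\,w \circ \xi} entrywise,
#' where \eqn{\xi} are the signal correlations.  (The minus sign is the sign
#' rule: gradient and signal correlations have opposite signs, so scaling the
#' signal correlations by `-w` reproduces the gradient, and scatter plots of
#' optimized noise correlations against `w o xi` reveal the sign-rule
#' alignment at small correlation strength.)  Computed as the elementwise
#' ratio \eqn{-G/\xi}; pairs with \eqn{\xi = 0} but nonzero gradient are
#' flagged `NA` (weight undefined).
#'
#' @inheritParams info_eval
#' @return pair vector of positive weights (`NA` where undefined), with
#'   attribute `undefined_pairs`.
#' @export
rescaling_weights <- function(stats, measure = c("fisher", "ole", "mutual")) {
  measure <- match.arg(measure)
  G <- info_gradient(stats, measure)
  xi <- signal_correlations(stats, measure)
  w <- -G / xi
  bad <- which(!is.finite(w) | xi == 0)
  if (length(bad)) {
    w[bad] <- NA_real_
    warning(length(bad), " pair(s) have zero signal correlation; ",
            "rescaling weight undefined there")
  }
  structure(w, undefined_pairs = bad)
}
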