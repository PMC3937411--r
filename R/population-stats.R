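# Numerical tolerances used package-wide.  A symmetric matrix is treated as
# positive semidefinite when its smallest eigenvalue is >= -PSD_TOL * lambda_max,
# and as singular (for inversion) when lambda_min < SING_TOL * lambda_max.
# The boundary of the spectrahedron is declared at |lambda_min| <= BOUNDARY_TOL
# * lambda_max.  The theory assumes exact definiteness; finite precision needs
# explicit cutoffs.
.psd_tol <- 1e-9
.sing_tol <- 1e-12
.boundary_tol <- 1e-8

.sym <- function(M) (M + t(M)) / 2

.eig_range <- function(M) {
  ev <- eigen(.sym(M), symmetric = TRUE, only.values = TRUE)$values
  c(min = min(ev), max = max(ev))
}

# Solve M x = b for a symmetric matrix that must be positive definite
# (relative to the singularity cutoff); `what` names the matrix in errors.
.pd_solve <- function(M, b, what = "matrix") {
  er <- .eig_range(M)
  scale <- max(abs(er["max"]), .Machine$double.xmin)
  if (er["min"] < .sing_tol * scale) {
    stop(what, " is not positive definite (min eigenvalue ",
         format(er["min"], digits = 4), ")", call. = FALSE)
  }
  solve(.sym(M), b)
}

.pd_logdet <- function(M, what = "matrix") {
  ev <- eigen(.sym(M), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(what, " is singular; log-determinant undefined", call. = FALSE)
  }
  sum(log(ev))
}

#' Sufficient statistics of a population-coding problem
#'
#' Bundles the stimulus-side quantities of a coding problem that are held
#' fixed while noise correlations vary: the local tuning sensitivities
#' \eqn{f'} (an \eqn{N \times K} matrix, one row per neuron), the
#' response--stimulus cross-covariance \eqn{L} (\eqn{N \times K}), the
#' covariance of the mean response \eqn{C^\mu} (\eqn{N \times N}), the noise
#' variances (diagonal of \eqn{C^n}, units response^2), and the stimulus
#' covariance \eqn{C^s} (\eqn{K \times K}).  Only the components needed by a
#' given operation are required; missing ones may be `NULL` and the relevant
#' functions will signal an informative error.
#'
#' @param noise_vars numeric vector of strictly positive noise variances,
#'   one per neuron.
#' @param sensitivities `N x K` matrix (or length-`N` vector for `K = 1`) of
#'   tuning-curve derivatives.
#' @param cross_cov `N x K` matrix (or vector) of response--stimulus
#'   covariances.
#' @param mean_resp_cov `N x N` symmetric positive semidefinite covariance of
#'   the mean (tuned) response.
#' @param stim_cov `K x K` symmetric positive definite stimulus covariance
#'   (a scalar for `K = 1`).
#' @return object of class `population_stats` with fields `n_neurons`,
#'   `stim_dim`, `sensitivities`, `cross_cov`, `mean_resp_cov`, `noise_vars`,
#'   `stim_cov`.
#' @export
population_stats <- function(noise_vars, sensitivities = NULL,
                             cross_cov = NULL, mean_resp_cov = NULL,
                             stim_cov = NULL) {
  noise_vars <- as.numeric(noise_vars)
  n <- length(noise_vars)
  if (n < 1 || any(!is.finite(noise_vars)) || any(noise_vars <= 0)) {
    stop("noise_vars must be a vector of strictly positive reals")
  }
  as_nk <- function(x, name) {
    if (is.null(x)) return(NULL)
    x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
    if (nrow(x) != n) stop(name, " must have one row per neuron (N = ", n, ")")
    storage.mode(x) <- "double"
    x
  }
  sensitivities <- as_nk(sensitivities, "sensitivities")
  cross_cov <- as_nk(cross_cov, "cross_cov")
  k <- unique(c(
    if (!is.null(sensitivities)) ncol(sensitivities),
    if (!is.null(cross_cov)) ncol(cross_cov)
  ))
  if (length(k) > 1) stop("sensitivities and cross_cov disagree on stimulus dimension")
  if (length(k) == 0) k <- if (!is.null(stim_cov)) nrow(as.matrix(stim_cov)) else 1L
  if (!is.null(mean_resp_cov)) {
    mean_resp_cov <- .sym(as.matrix(mean_resp_cov))
    if (!all(dim(mean_resp_cov) == c(n, n))) stop("mean_resp_cov must be N x N")
    er <- .eig_range(mean_resp_cov)
    if (er["min"] < -.psd_tol * max(er["max"], 1)) {
      stop("mean_resp_cov is not positive semidefinite")
    }
  }
  if (!is.null(stim_cov)) {
    stim_cov <- .sym(as.matrix(stim_cov))
    if (!all(dim(stim_cov) == c(k, k))) stop("stim_cov must be K x K")
    er <- .eig_range(stim_cov)
    if (er["min"] <= .sing_tol * max(er["max"], 1)) {
      stop("stim_cov must be positive definite")
    }
  }
  structure(
    list(n_neurons = as.integer(n), stim_dim = as.integer(k),
         sensitivities = sensitivities, cross_cov = cross_cov,
         mean_resp_cov = mean_resp_cov, noise_vars = noise_vars,
         stim_cov = stim_cov),
    class = "population_stats"
  )
}

#' @export
print.population_stats <- function(x, ...) {
  cat("<population_stats> N =", x$n_neurons, " K =", x$stim_dim, "\n")
  have <- c(sensitivities = !is.null(x$sensitivities),
            cross_cov = !is.null(x$cross_cov),
            mean_resp_cov = !is.null(x$mean_resp_cov),
            stim_cov = !is.null(x$stim_cov))
  cat("  components:", paste(names(have)[have], collapse = ", "), "\n")
  invisible(x)
}

.need <- function(stats, field) {
  if (is.null(stats[[field]])) {
    stop("population_stats is missing '", field, "', required here",
         call. = FALSE)
  }
  stats[[field]]
}

#' Build a noise covariance from variances and pairwise correlations
#'
#' Inverse of the usual diagonal normalization: given per-neuron variances
#' \eqn{\sigma_i^2} and pairwise correlations \eqn{\rho_{ij}}, returns
#' \eqn{C^n_{ij} = \rho_{ij}\sqrt{\sigma_i^2\sigma_j^2}} with the variances on
#' the diagonal.  Positive semidefiniteness is deliberately *not* enforced
#' here; admissibility is the spectrahedron module's job (see
#' [classify_corr()]).
#'
#' @param noise_vars positive noise variances (length `N`).
#' @param corr pair vector of correlations in `[-1, 1]` (length `N*(N-1)/2`),
#'   or an `N x N` correlation matrix.
#' @return object of class `noise_cov` with fields `cov`, `corr` (matrix with
#'   unit diagonal) and `vars`.
#' @export
noise_cov_from <- function(noise_vars, corr) {
  noise_vars <- as.numeric(noise_vars)
  n <- length(noise_vars)
  if (any(noise_vars <= 0)) stop("noise_vars must be strictly positive")
  R <- if (is.matrix(corr)) .sym(corr) else pairvec_to_corrmat(as.numeric(corr), n)
  if (nrow(R) != n) stop("correlation dimension does not match noise_vars")
  off <- corrmat_to_pairvec(R)
  if (any(abs(off) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  if (any(abs(diag(R) - 1) > 1e-12)) stop("correlation matrix must have unit diagonal")
  s <- sqrt(noise_vars)
  structure(
    list(cov = .sym(R * tcrossprod(s)), corr = R, vars = noise_vars),
    class = "noise_cov"
  )
}

#' @export
print.noise_cov <- function(x, ...) {
  er <- .eig_range(x$cov)
  cat("<noise_cov> N =", length(x$vars),
      " min eig =", format(er["min"], digits = 4), "\n")
  invisible(x)
}

# Coerce `noise` arguments: a noise_cov object, a pair vector of correlations,
# or NULL (independent noise).
.as_noise <- function(stats, noise) {
  if (is.null(noise)) {
    return(noise_cov_from(stats$noise_vars, rep(0, stats$n_neurons *
                                                  (stats$n_neurons - 1) / 2)))
  }
  if (inherits(noise, "noise_cov")) {
    if (length(noise$vars) != stats$n_neurons) {
      stop("noise covariance dimension does not match population")
    }
    return(noise)
  }
  noise_cov_from(stats$noise_vars, noise)
}
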