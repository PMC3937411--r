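# Synthetic populations: heterogeneous von Mises tuning with Poisson count
# variability for a circular (direction-of-motion) stimulus, plus small
# 3-neuron example fixtures and generic random problem instances used by the
# test and acceptance suites.

#' Sample a heterogeneous von Mises tuning ensemble
#'
#' Per-neuron tuning curves for a direction stimulus,
#' \deqn{f_i(\theta) = \alpha_i \exp[\kappa_i(\cos(\theta - \phi_i) - 1)]}
#' (spikes/s; \eqn{\alpha_i} is the peak rate).  Amplitudes are chi-square
#' with 3 degrees of freedom scaled to a mean of 19 spikes/s; widths are
#' log-normal with mean 2 and standard deviation 2 *of the underlying normal*
#' (`meanlog = 2`, `sdlog = 2`); preferred directions are equally spaced on
#' `[0, 2*pi)`.  Spike counts are Poisson over a counting window (default
#' 100 ms), so count variance equals mean count.
#'
#' @param n number of neurons (`>= 2`).
#' @param seed optional integer seed.
#' @param window_ms spike-count window in milliseconds.
#' @return object of class `tuning_ensemble`: list with `n_neurons`,
#'   `alphas` (spikes/s), `kappas`, `phis` (radians), `window_ms`.
#' @export
sample_population <- function(n, seed = NULL, window_ms = 100) {
  if (n < 2) stop("need at least 2 neurons")
  if (!is.null(seed)) set.seed(seed)
  alphas <- (19 / 3) * stats::rchisq(n, df = 3)
  kappas <- stats::rlnorm(n, meanlog = 2, sdlog = 2)
  phis <- 2 * pi * (0:(n - 1)) / n
  structure(list(n_neurons = as.integer(n), alphas = alphas, kappas = kappas,
                 phis = phis, window_ms = window_ms),
            class = "tuning_ensemble")
}

#' @export
print.tuning_ensemble <- function(x, ...) {
  cat("<tuning_ensemble> N =", x$n_neurons, " window =", x$window_ms, "ms\n")
  invisible(x)
}

#' Population statistics of a von Mises ensemble
#'
#' The stimulus is the 2-D unit vector \eqn{s = (\cos\theta, \sin\theta)}
#' with \eqn{\theta} uniform on the circle (so `K = 2` and
#' \eqn{C^s = I_2/2}).  Mean spike counts are `rate * window`; the
#' response--stimulus cross-covariance `L` and the mean-response covariance
#' `C^\mu` are computed by quadrature over a uniform periodic grid (for which
#' the trapezoid and rectangle rules coincide), and Poisson variability sets
#' the noise variances equal to the mean counts.
#'
#' @param ens a [sample_population()] ensemble.
#' @param grid_size number of stimulus grid points (`>= 64`).
#' @return a [population_stats()] object (with `sensitivities = NULL`; the
#'   global OLE / mutual-information measures are the natural ones here).
#' @export
population_moments <- function(ens, grid_size = 512) {
  if (!inherits(ens, "tuning_ensemble")) stop("ens must be a tuning_ensemble")
  if (grid_size < 64) stop("grid_size must be >= 64")
  theta <- 2 * pi * (0:(grid_size - 1)) / grid_size
  Tw <- ens$window_ms / 1000
  # rates: N x G
  rate <- ens$alphas * exp(ens$kappas * (cos(outer(ens$phis, theta, "-")) - 1))
  if (all(rate == 0)) stop("degenerate all-zero tuning")
  counts <- rate * Tw
  mu_bar <- rowMeans(counts)
  S <- rbind(cos(theta), sin(theta))          # 2 x G, zero mean on the grid
  L <- counts %*% t(S) / grid_size            # N x 2
  Cmu <- tcrossprod(counts) / grid_size - tcrossprod(mu_bar)
  Cs <- tcrossprod(S) / grid_size             # = I/2 exactly on the grid
  population_stats(noise_vars = mu_bar, cross_cov = L,
                   mean_resp_cov = .sym(Cmu), stim_cov = .sym(Cs))
}

# ---------------------------------------------------------------------------
# 3-neuron example fixtures.  These are SYNTHETIC worked examples: the
# numeric entries are package choices constructed to exhibit one regime of
# interest each: see ?fixture_population.

.fixture_fig1 <- function(case) {
  mean1 <- c(2, 2, 3)
  mean2 <- c(3, 3, 2)                          # sensitivity f' = (1, 1, -1)
  vars <- c(1, 1, 1)
  corr <- switch(case,
    A = c(0, 0, 0),                            # independent baseline
    B = c(0.3, -0.3, -0.3),                    # anti-sign-rule: harms coding
    C = c(-0.3, 0.3, 0.3),                     # sign-rule: improves coding
    D = c(0.7, 0.7, 0.7))                      # violates SR yet improves
  stats <- population_stats(noise_vars = vars,
                            sensitivities = mean2 - mean1)
  list(stats = stats, noise_corr = corr, mean_stim1 = mean1,
       mean_stim2 = mean2)
}

.fixture_fig2 <- function() {
  Cmu <- matrix(c(1, 0.5, 0.25,
                  0.5, 1, 0.5,
                  0.25, 0.5, 1), 3, 3)
  L <- c(1, 0.8, 0.5)
  stats <- population_stats(noise_vars = c(1, 1, 1), cross_cov = L,
                            mean_resp_cov = Cmu, stim_cov = 1)
  slice <- function(rho12, rho_shared) c(rho12, rho_shared, rho_shared)
  list(stats = stats, slice = slice)
}

.fixture_fig3 <- function(panel) {
  L <- if (panel == "A") c(1, 1, 1) else c(3, 1, 1)
  stats <- population_stats(noise_vars = c(1, 1, 1), cross_cov = L,
                            mean_resp_cov = diag(3), stim_cov = 1)
  list(stats = stats)
}

#' Three-neuron example fixtures
#'
#' Small *synthetic* worked examples exercising the main phenomena; the
#' numeric entries are package choices (flagged by the `synthetic` field),
#' each constructed to exhibit one regime of interest:
#' \itemize{
#'   \item `fig1_caseA..D`: three neurons discriminating two stimuli (two
#'     mean-response vectors, unit variances) under four correlation
#'     structures -- independent (A), anti-sign-rule/harmful (B),
#'     sign-rule/beneficial (C), and sign-rule-violating yet beneficial (D).
#'   \item `fig2`: scalar-stimulus OLE example with unit variances and the
#'     two-dimensional correlation slice `rho13 = rho23` (returned as the
#'     `slice` function); the information surface is convex on the slice and
#'     its gradient at independence obeys the sign rule.
#'   \item `fig3_A`, `fig3_B`: unit noise variances, `C^mu = I`; panel A's
#'     cancellation lengths satisfy the strict polygon inequality (the
#'     noise-free bound is attained on the spectrahedron boundary) while
#'     panel B's violate it (the bound is unattainable).
#' }
#'
#' @param name one of `"fig1_caseA"`, `"fig1_caseB"`, `"fig1_caseC"`,
#'   `"fig1_caseD"`, `"fig2"`, `"fig3_A"`, `"fig3_B"`.
#' @return list of class `fixture` with at least `name` and `stats` (a
#'   [population_stats()]); fig1 fixtures add `noise_corr`, `mean_stim1`,
#'   `mean_stim2`; fig2 adds the `slice` parameterization.
#' @export
fixture_population <- function(name) {
  fx <- switch(name,
    fig1_caseA = .fixture_fig1("A"),
    fig1_caseB = .fixture_fig1("B"),
    fig1_caseC = .fixture_fig1("C"),
    fig1_caseD = .fixture_fig1("D"),
    fig2 = .fixture_fig2(),
    fig3_A = .fixture_fig3("A"),
    fig3_B = .fixture_fig3("B"),
    stop("unknown fixture name: ", name))
  structure(c(list(name = name, synthetic = TRUE), fx), class = "fixture")
}

#' Random population-statistics instances
#'
#' Generic random problem instances for property tests and demonstrations.
#' Realizability is respected: `C^mu` is built as
#' \eqn{W C^s W^\top + E + \delta I} with `L = W C^s` and PSD extra tuning
#' variance `E`, so the implied joint covariance is a true covariance and the
#' OLE mean squared error is nonnegative.  With
#' `consistent = TRUE` the extra variance is dropped
#' (\eqn{C^\mu = L (C^s)^{-1} L^\top}), giving the exactly jointly Gaussian
#' case required by the mutual-information measure (note `C^mu` is then rank
#' `K`).
#'
#' @param n neurons; `k` stimulus dimensions.
#' @param k stimulus dimension.
#' @param consistent build exactly jointly-Gaussian-consistent statistics.
#' @param seed optional integer seed.
#' @return a [population_stats()] object with all components populated.
#' @export
random_population_stats <- function(n, k = 1, consistent = FALSE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(stats::rnorm(k * k), k, k)
  Cs <- .sym(crossprod(B) + diag(0.5, k))
  W <- matrix(stats::rnorm(n * k), n, k)
  L <- W %*% Cs
  Cmu <- L %*% solve(Cs, t(L))
  if (!consistent) {
    E <- matrix(stats::rnorm(n * n), n, n)
    Cmu <- Cmu + .sym(crossprod(E)) / n + diag(0.1, n)
  }
  population_stats(
    noise_vars = stats::runif(n, 0.5, 2),
    sensitivities = matrix(stats::rnorm(n * k), n, k),
    cross_cov = L, mean_resp_cov = .sym(Cmu), stim_cov = Cs
  )
}
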