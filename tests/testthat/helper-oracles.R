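# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: finite differences for gradients, bisection for
# boundary steps, Monte-Carlo simulation for the OLE error, direct SVD for
# ranks.

# central finite differences of a scalar information measure w.r.t. the
# pair-vector correlations
fd_gradient <- function(stats, measure, rho, h = 1e-5) {
  vapply(seq_along(rho), function(i) {
    e <- rep(0, length(rho)); e[i] <- h
    (info_eval(stats, measure, rho + e) -
       info_eval(stats, measure, rho - e)) / (2 * h)
  }, numeric(1))
}

# bisection on the exact eigenvalue sign, independent of the closed-form
# eigenproblem route (and of classify_corr's boundary tolerance)
bisect_max_step <- function(corr0, direction, t_hi = NULL, iter = 80) {
  adm <- function(t) {
    v <- corr0 + t * direction
    if (any(abs(v) > 1)) return(FALSE)
    R <- pairvec_to_corrmat(v)
    min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= -1e-13
  }
  if (is.null(t_hi)) {
    t_hi <- 1
    while (adm(t_hi)) t_hi <- t_hi * 2
  }
  lo <- 0; hi <- t_hi
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (adm(mid)) lo <- mid else hi <- mid
  }
  lo
}

# sample from N(0, Sigma) via eigendecomposition (no MASS dependency)
rmvn <- function(n, Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma))
  matrix(rnorm(n * nrow(Sigma)), n) %*% t(A)
}

# Monte-Carlo mean squared error of the OLE readout on simulated draws from
# the joint model implied by (L, Cmu, Cs, Cn)
mc_ole_mse <- function(stats, noise, nsim = 40000) {
  Cs <- stats$stim_cov
  L <- stats$cross_cov
  W <- L %*% solve(Cs)
  Ce <- stats$mean_resp_cov - L %*% solve(Cs, t(L))
  S <- rmvn(nsim, Cs)
  X <- S %*% t(W) + rmvn(nsim, Ce) + rmvn(nsim, noise$cov)
  A <- ole_solution(stats, noise)
  Shat <- X %*% A
  mean(rowSums((S - Shat)^2))
}

# random strict-feasible cancellation instance: Cmu = I so the noise-free
# readout equals L exactly
random_cancel_stats <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    A <- runif(n, 0.2, 1.5) * sample(c(-1, 1), n, replace = TRUE)
    vars <- runif(n, 0.5, 2)
    q <- sqrt(vars) * abs(A)
    if (2 * max(q) < sum(q)) break
  }
  population_stats(noise_vars = vars, cross_cov = A,
                   mean_resp_cov = diag(n), stim_cov = 1)
}
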