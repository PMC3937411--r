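test_that("noise_cov_from builds covariances from variances and correlations", {
  nc <- noise_cov_from(c(1, 1, 1), c(0, 0, 0))
  expect_equal(nc$cov, diag(3))

  nc <- noise_cov_from(c(4, 1), 0.5)
  expect_equal(nc$cov[1, 2], 1.0)   # 0.5 * sqrt(4 * 1)
  expect_equal(diag(nc$cov), c(4, 1))

  nc <- noise_cov_from(c(1, 1), -1)  # perfectly anti-correlated pair
  expect_equal(nc$cov, matrix(c(1, -1, -1, 1), 2))

  expect_error(noise_cov_from(c(1, 1), 1.5), "\\[-1, 1\\]")
  expect_error(noise_cov_from(c(1, 1, 1), c(0, 0)), "length|dimension")
})

test_that("linear Fisher information matches closed forms", {
  st <- population_stats(noise_vars = c(1, 1, 1),
                         sensitivities = c(1, 0, 0))
  expect_equal(linear_fisher(st)$value, 1)

  st2 <- population_stats(noise_vars = c(1, 1), sensitivities = c(1, 1))
  for (r in c(-0.9, -0.5, 0, 0.3, 0.8)) {
    expect_equal(linear_fisher(st2, r)$value, 2 / (1 + r), tolerance = 1e-12)
  }
  # negative correlation boosts information past the independent value
  expect_equal(linear_fisher(st2, -0.5)$value, 4)
  expect_gt(linear_fisher(st2, -0.5)$value, linear_fisher(st2, 0)$value)

  expect_error(linear_fisher(st2, 1), "not positive definite")
})

test_that("OLE solution and information honour the cancellation identity", {
  st <- population_stats(noise_vars = c(1, 1), cross_cov = c(1, 0),
                         mean_resp_cov = diag(2), stim_cov = 1)
  expect_equal(drop(ole_solution(st, zero_noise = TRUE)), c(1, 0))

  # anti-correlated pair: C^n annihilates the readout, so the OLE readout
  # equals the noise-free one, A = (C^mu)^{-1} L = (1, 1), and the OLE
  # information equals the noise-free bound (= 2).  Values frozen from the
  # exact 2x2 solve.
  st2 <- population_stats(noise_vars = c(1, 1), cross_cov = c(1, 1),
                          mean_resp_cov = diag(2), stim_cov = 4)
  nc <- noise_cov_from(c(1, 1), -1)
  A <- ole_solution(st2, nc)
  expect_equal(drop(A), c(1, 1), tolerance = 1e-12)
  expect_equal(drop(nc$cov %*% A), c(0, 0), tolerance = 1e-12)
  expect_equal(ole_info(st2, nc)$value, 2, tolerance = 1e-12)
  expect_equal(ole_info(st2, nc)$value, noise_free_bound(st2),
               tolerance = 1e-12)

  st3 <- population_stats(noise_vars = c(1, 1), cross_cov = c(0, 0),
                          mean_resp_cov = diag(2), stim_cov = 1)
  expect_equal(drop(ole_solution(st3)), c(0, 0))
  expect_equal(ole_info(st3)$value, 0)

  # zero-noise ole_info equals the bound exactly
  set.seed(41)
  st4 <- random_population_stats(5, 2)
  expect_equal(ole_info(st4, zero_noise = TRUE)$value, noise_free_bound(st4))
})

test_that("OLE mean squared error matches definition and simulation", {
  # perfect 1-neuron linear code: zero error
  st <- population_stats(noise_vars = 1e-12 + 1, cross_cov = 1,
                         mean_resp_cov = 1, stim_cov = 1)
  expect_equal(ole_mse(st, zero_noise = TRUE), 0, tolerance = 1e-12)

  st2 <- population_stats(noise_vars = c(1, 2), cross_cov = c(0, 0),
                          mean_resp_cov = diag(2), stim_cov = 1.7)
  expect_equal(ole_mse(st2), 1.7)

  set.seed(7)
  st3 <- random_population_stats(4, 1)
  rho <- random_admissible(4, 4)$corr * 0.6
  nc <- noise_cov_from(st3$noise_vars, rho)
  mse <- ole_mse(st3, nc)
  mc <- mc_ole_mse(st3, nc, nsim = 60000)
  expect_gt(mse, 0)
  expect_lt(abs(mse - mc) / mse, 0.05)
})

test_that("Gaussian mutual information: closed form, symmetry, limits", {
  # independence
  st0 <- population_stats(noise_vars = c(1, 1), cross_cov = c(0, 0),
                          mean_resp_cov = matrix(0, 2, 2), stim_cov = 1)
  expect_equal(mutual_info_gaussian(st0), 0)

  # one-neuron Gaussian channel: 1/2 log(1 + s2/n2)
  for (s2 in c(0.5, 2)) for (n2 in c(0.3, 1.5)) {
    st <- population_stats(noise_vars = n2, cross_cov = s2,
                           mean_resp_cov = s2, stim_cov = s2)
    expect_equal(mutual_info_gaussian(st), 0.5 * log(1 + s2 / n2),
                 tolerance = 1e-12)
  }

  # symmetry under exchanging stimulus and response blocks:
  # 1/2 log det(Ctot)/det(Cn) == 1/2 log det(Cs)/det(Cs - L' Ctot^-1 L)
  set.seed(11)
  st <- random_population_stats(5, 2, consistent = TRUE)
  rho <- random_admissible(5, 5)$corr * 0.5
  nc <- noise_cov_from(st$noise_vars, rho)
  mi <- mutual_info_gaussian(st, nc)
  Ctot <- nc$cov + st$mean_resp_cov
  other <- 0.5 * (determinant(st$stim_cov)$modulus -
    determinant(st$stim_cov - t(st$cross_cov) %*%
                  solve(Ctot, st$cross_cov))$modulus)
  expect_equal(mi, as.numeric(other), tolerance = 1e-10)

  # small-signal limit: leading Taylor term proportional to the OLE
  # information (ratio -> 1 against I_OLE / (2 sigma_s^2) for scalar s)
  s2 <- 1.3
  L <- c(1, -0.5, 0.25)
  for (eps in c(1e-2, 1e-3)) {
    Le <- eps * L
    st_eps <- population_stats(noise_vars = c(1, 2, 1.5), cross_cov = Le,
                               mean_resp_cov = tcrossprod(Le) / s2,
                               stim_cov = s2)
    mi <- mutual_info_gaussian(st_eps)
    lead <- ole_info(st_eps)$value / (2 * s2)
    expect_equal(mi / lead, 1, tolerance = 10 * eps)
  }

  # contract violations
  st_bad <- population_stats(noise_vars = c(1, 1), cross_cov = c(1, 1),
                             mean_resp_cov = diag(2), stim_cov = 1)
  expect_error(mutual_info_gaussian(st_bad), "inconsistent joint covariance")
  st_ok <- population_stats(noise_vars = c(1, 1), cross_cov = c(1, 1),
                            mean_resp_cov = matrix(1, 2, 2), stim_cov = 1)
  expect_warning(val <- mutual_info_gaussian(st_ok, noise = -1), "singular")
  expect_identical(val, Inf)
})

test_that("signal correlations follow the normalized sensitivity vectors", {
  st <- population_stats(noise_vars = c(1, 1),
                         sensitivities = rbind(c(1, 0), c(0, 1)))
  expect_equal(as.numeric(signal_correlations(st, "fisher")), 0)

  st2 <- population_stats(noise_vars = c(1, 1), sensitivities = c(2, -3))
  expect_equal(as.numeric(signal_correlations(st2, "fisher")), -1)

  st3 <- population_stats(noise_vars = c(1, 1),
                          sensitivities = rbind(c(1, 1), c(1, 1)))
  expect_equal(as.numeric(signal_correlations(st3, "fisher")), 1)

  st4 <- population_stats(noise_vars = c(1, 1), sensitivities = c(1, 0))
  expect_warning(xi <- signal_correlations(st4, "fisher"), "zero-norm")
  expect_true(is.na(xi[1]))
  expect_equal(attr(xi, "undefined_pairs"), 1L)
})

test_that("information gradients match finite differences and the sign rule", {
  st <- population_stats(noise_vars = c(1, 1), sensitivities = c(1, 1))
  expect_equal(as.numeric(info_gradient(st, "fisher")), -2)

  set.seed(5)
  for (rep in 1:6) {
    n <- sample(3:6, 1)
    k <- sample(1:2, 1)
    for (m in c("fisher", "ole", "mutual")) {
      stx <- random_population_stats(n, k, consistent = (m == "mutual"))
      # at independence and at a random interior point
      for (rho in list(NULL, 0.5 * random_admissible(n, n)$corr)) {
        g <- info_gradient(stx, m, rho)
        rho0 <- if (is.null(rho)) rep(0, n * (n - 1) / 2) else rho
        fd <- fd_gradient(stx, m, rho0)
        expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-6)
      }
      # sign-rule sign property at independence
      g0 <- info_gradient(stx, m)
      xi <- signal_correlations(stx, m)
      nz <- which(abs(xi) > 1e-12 & abs(g0) > 1e-12)
      expect_true(all(sign(g0[nz]) == -sign(xi[nz])))
    }
  }
})

test_that("the noise-free bound dominates OLE information", {
  st <- population_stats(noise_vars = rep(1, 3), cross_cov = diag(3),
                         mean_resp_cov = diag(3), stim_cov = diag(3))
  expect_equal(noise_free_bound(st), 3)
  st0 <- population_stats(noise_vars = rep(1, 3),
                          cross_cov = matrix(0, 3, 1),
                          mean_resp_cov = diag(3), stim_cov = 1)
  expect_equal(noise_free_bound(st0), 0)

  set.seed(13)
  st2 <- random_population_stats(6, 1)
  b <- noise_free_bound(st2)
  for (i in 1:100) {
    rho <- random_admissible(6, sample(3:6, 1))$corr
    expect_lte(ole_info(st2, rho)$value, b + 1e-9 * max(1, b))
  }
})

test_that("correlation strength is the Euclidean pair norm", {
  expect_equal(correlation_strength(rep(0, 10)), 0)
  expect_equal(correlation_strength(-1), 1)
  expect_equal(correlation_strength(c(0.3, 0.4)), 0.5)
})

test_that("rescaling weights are positive and reproduce the gradient", {
  st <- population_stats(noise_vars = c(1, 1), sensitivities = c(1, 1))
  expect_equal(as.numeric(rescaling_weights(st, "fisher")), 2)

  # homogeneous population: all weights equal by symmetry
  sth <- population_stats(noise_vars = rep(1.3, 4),
                          sensitivities = rep(0.7, 4))
  wh <- as.numeric(rescaling_weights(sth, "fisher"))
  expect_equal(wh, rep(wh[1], 6))

  set.seed(21)
  for (m in c("fisher", "ole", "mutual")) {
    stx <- random_population_stats(5, 2, consistent = (m == "mutual"))
    w <- rescaling_weights(stx, m)
    xi <- signal_correlations(stx, m)
    G <- info_gradient(stx, m)
    expect_true(all(w > 0))
    expect_equal(as.numeric(-w * xi), as.numeric(G), tolerance = 1e-12)
  }

  st_flag <- population_stats(noise_vars = c(1, 1),
                              sensitivities = rbind(c(1, 0), c(0, 1)))
  expect_warning(wf <- rescaling_weights(st_flag, "fisher"), "zero signal")
  expect_true(is.na(wf[1]))
})
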