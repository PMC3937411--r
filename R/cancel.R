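# Noise cancellation: correlation structures whose covariance annihilates the
# noise-free OLE readout (C^n A = 0, A = (C^mu)^{-1} L), so that the optimal
# linear estimator performs exactly as it would with deterministic responses.
# Existence reduces, for a scalar stimulus, to a polygon inequality on
# q_i = sigma_i |A_i|: vectors of lengths q_i can close into a loop iff
# 2 max q <= sum q.  The constructive solution builds such a closing polygon,
# normalizes its directions, and sign-flips the Gram matrix by the readout
# signs.

#' Cancellation lengths q and readout signs
#'
#' For a scalar stimulus, computes \eqn{q_i = \sigma_i |A_i|} (noise standard
#' deviation times the magnitude of the noise-free readout weight) and the
#' sign pattern of the readout \eqn{A = (C^\mu)^{-1} L}.  These lengths decide
#' whether noise-canceling correlations exist (see [cancel_feasibility()]).
#'
#' @inheritParams info_eval
#' @return object of class `qvector`: list with `q` (nonnegative vector),
#'   `signs` (in -1/0/+1), `n_zero`, and the readout `A`.
#' @export
q_values <- function(stats) {
  if (stats$stim_dim != 1) {
    stop("q_values requires a scalar stimulus (K = 1); the cancellation ",
         "feasibility theory is stated for scalar stimuli")
  }
  A <- drop(ole_solution(stats, zero_noise = TRUE))
  q <- sqrt(stats$noise_vars) * abs(A)
  structure(list(q = q, signs = sign(A), n_zero = sum(q == 0), A = A),
            class = "qvector")
}

#' @export
print.qvector <- function(x, ...) {
  cat("<qvector> N =", length(x$q), " zeros =", x$n_zero,
      " case =", cancel_feasibility(x), "\n")
  invisible(x)
}

#' Feasibility of noise cancellation
#'
#' The polygon condition on the cancellation lengths: `"strict"` if
#' `2*max(q) < sum(q)`, `"equality"` if equal, `"infeasible"` otherwise.
#' The degenerate all-zero case (zero readout, flat objective) is flagged
#' `"degenerate"` separately.
#'
#' @param q a `qvector` from [q_values()], or a plain nonnegative vector.
#' @param tol relative tolerance for the equality case.
#' @return one of `"strict"`, `"equality"`, `"infeasible"`, `"degenerate"`.
#' @export
cancel_feasibility <- function(q, tol = 1e-12) {
  qv <- if (inherits(q, "qvector")) q$q else as.numeric(q)
  if (any(qv < 0)) stop("q must be nonnegative")
  s <- sum(qv)
  if (s == 0) return("degenerate")
  m <- max(qv)
  if (abs(2 * m - s) <= tol * s) return("equality")
  if (2 * m < s) return("strict")
  "infeasible"
}

#' Closing polygon: vectors of prescribed lengths summing to zero
#'
#' Constructs `N` vectors \eqn{v_i \in R^{N-1}} with \eqn{\|v_i\| = q_i} and
#' \eqn{\sum_i v_i = 0}, spanning the whole of \eqn{R^{N-1}} (so the Gram
#' matrix of their directions has the generic rank `N-1`).  Requires the
#' strict polygon inequality `2*max(q) < sum(q)`, all `q > 0`, `N >= 3`.
#'
#' The construction is a deterministic version of the inductive proof: sort
#' descending; repeatedly merge the two smallest lengths into one virtual
#' length `t` chosen at the midpoint of its feasible open interval (so the
#' reduced list stays strictly polygon-feasible and the merged pair forms a
#' strict triangle); resolve the base case as a triangle via the law of
#' cosines; then unfold each merge in a fresh standard-basis dimension.
#'
#' @param q positive lengths (length `N >= 3`) satisfying the strict
#'   inequality.
#' @return `N x (N-1)` matrix whose rows are the vectors, in the order of `q`.
#' @export
closing_polygon <- function(q) {
  q <- as.numeric(q)
  n <- length(q)
  if (n < 3) stop("need at least 3 lengths")
  if (any(q <= 0)) stop("all lengths must be strictly positive")
  if (!(2 * max(q) < sum(q))) {
    stop("strict polygon inequality 2*max(q) < sum(q) violated")
  }
  ord <- order(q, decreasing = TRUE)
  qs <- q[ord]

  # Triangle with side lengths (a, b, c): v1 along +x, v2 by law of cosines,
  # v3 closes the loop.  Returns rows in 2 columns.
  triangle <- function(a, b, c) {
    ca <- (c^2 - a^2 - b^2) / (2 * a * b)
    ca <- min(1, max(-1, ca))
    sa <- sqrt(max(0, 1 - ca^2))
    v1 <- c(a, 0)
    v2 <- c(b * ca, b * sa)
    rbind(v1, v2, -(v1 + v2))
  }

  # Recursive construction in dim = length(qs) - 1; qs sorted descending.
  build <- function(qs) {
    k <- length(qs)
    if (k == 3) return(triangle(qs[1], qs[2], qs[3]))
    s_head <- sum(qs[1:(k - 2)])
    lo <- max(abs(qs[k - 1] - qs[k]), 2 * qs[1] - s_head, 0)
    hi <- min(qs[k - 1] + qs[k], s_head)
    t_ <- (lo + hi) / 2
    reduced <- sort(c(qs[1:(k - 2)], t_), decreasing = TRUE)
    # remember where the virtual length t_ sits after sorting (first match)
    pos_t <- match(t_, reduced)
    Vr <- build(reduced)                       # (k-1) x (k-2)
    Vr <- cbind(Vr, 0)                         # embed in k-1 dims
    w <- Vr[pos_t, ]
    keep <- Vr[-pos_t, , drop = FALSE]
    # split w (length t_) into two vectors of lengths qs[k-1], qs[k]
    tlen <- sqrt(sum(w^2))
    if (tlen < 1e-300) {
      # degenerate virtual edge: split into an opposed pair in the new dim
      a <- numeric(k - 1); a[k - 1] <- qs[k - 1]
      b <- numeric(k - 1); b[k - 1] <- -qs[k]
      # only valid if qs[k-1] == qs[k]; midpoint rule makes tlen>0 otherwise
      va <- a; vb <- w - a
    } else {
      what <- w / tlen
      comp <- (tlen^2 + qs[k - 1]^2 - qs[k]^2) / (2 * tlen)
      h <- sqrt(max(0, qs[k - 1]^2 - comp^2))
      znew <- numeric(k - 1); znew[k - 1] <- 1
      va <- comp * what + h * znew
      vb <- w - va
    }
    rbind(keep, va, vb)
  }

  Vs <- build(qs)                              # rows ordered: merges unfold
  # build() returns rows in an internal order: rows for the merged tail are
  # appended last.  Reconstruct the map: the recursion keeps the non-merged
  # (largest) lengths in sorted order and appends the split pair; since all
  # merges take the two smallest of the current sorted list, the final row
  # order corresponds to lengths in some permutation of qs.  Recover it by
  # matching norms greedily.
  nrm <- sqrt(rowSums(Vs^2))
  assign <- integer(n)
  used <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(nrm - qs[i]) + ifelse(used, Inf, 0)
    jj <- which.min(d)
    assign[i] <- jj
    used[jj] <- TRUE
  }
  if (max(abs(nrm[assign] - qs)) > 1e-8 * max(qs)) {
    stop("internal error: polygon construction norms do not match lengths")
  }
  V <- matrix(0, n, n - 1)
  V[ord, ] <- Vs[assign, , drop = FALSE]
  if (max(abs(colSums(V))) > 1e-8 * max(qs)) {
    stop("internal error: polygon does not close")
  }
  V
}

# Linear system C rho = b expressing C^n A = 0 over the pair vector rho.
# Row i: sum_{j != i} rho_{ij} sigma_i sigma_j A_j = -sigma_i^2 A_i.
# For K > 1 columns of A, rows are stacked per stimulus dimension.
.cancel_constraints <- function(A, noise_vars) {
  A <- if (is.matrix(A)) A else matrix(A, ncol = 1)
  n <- nrow(A); k <- ncol(A)
  s <- sqrt(noise_vars)
  idx <- pair_index(n)
  m <- nrow(idx)
  C <- matrix(0, n * k, m)
  b <- numeric(n * k)
  for (kk in seq_len(k)) {
    for (r in seq_len(n)) {
      row <- (kk - 1) * n + r
      hit_i <- which(idx[, 1] == r)
      hit_j <- which(idx[, 2] == r)
      C[row, hit_i] <- s[r] * s[idx[hit_i, 2]] * A[idx[hit_i, 2], kk]
      C[row, hit_j] <- s[r] * s[idx[hit_j, 1]] * A[idx[hit_j, 1], kk]
      b[row] <- -noise_vars[r] * A[r, kk]
    }
  }
  list(C = C, b = b)
}

#' Construct a noise-canceling correlation matrix
#'
#' Builds a unit-diagonal positive-semidefinite correlation matrix whose
#' covariance annihilates the noise-free OLE readout (`C^n A = 0`), so that
#' the OLE information equals the noise-free bound.  Strict case: Gram matrix
#' of the closing-polygon unit directions, sign-flipped by the readout signs;
#' neurons with `q = 0` are appended as an uncorrelated identity block.
#' Equality case: the unique solution on the nonzero block (all polygon
#' vectors collinear, the largest opposed to the rest) with the identity on
#' the zero block.  Infeasible lengths are an error.
#'
#' @inheritParams info_eval
#' @return object of class `cancel_solution`: list with `corr` (N x N
#'   matrix), `case`, `dimension` (of the convex set of canceling
#'   correlations), `basis` (list of pair-vector directions spanning the
#'   tangent space of that set at the solution), `q` (the `qvector`).
#' @export
construct_canceling <- function(stats) {
  qv <- q_values(stats)
  cs <- cancel_feasibility(qv)
  n <- stats$n_neurons
  if (cs == "infeasible") {
    stop("no noise-canceling correlations exist: 2*max(q) > sum(q)")
  }
  if (cs == "degenerate") {
    stop("readout is identically zero (L = 0): objective is trivially flat, ",
         "no canceling set is defined")
  }
  nz <- which(qv$q > 0)
  d <- qv$signs
  R <- diag(1, n)
  if (cs == "strict") {
    if (length(nz) < 3) stop("internal error: strict case needs >= 3 nonzero q")
    V <- closing_polygon(qv$q[nz])
    U <- V / qv$q[nz]
    G <- .sym(tcrossprod(U))
    diag(G) <- 1
    R[nz, nz] <- (d[nz] %o% d[nz]) * G
  } else {
    mx <- nz[which.max(qv$q[nz])]
    e <- d
    e[mx] <- -e[mx]
    R[nz, nz] <- (e[nz] %o% e[nz])
    diag(R) <- 1
  }
  dim_ <- canceling_set_dimension(stats)
  cm <- .cancel_constraints(qv$A, stats$noise_vars)
  ns <- .nullspace(cm$C)
  basis <- if (cs == "strict") {
    lapply(seq_len(ncol(ns)), function(j) ns[, j])
  } else {
    # equality case: the nonzero block is pinned to a rank-one matrix e e^T,
    # so the tangent directions are (a) scaling each zero neuron's coupling
    # along the e pattern and (b) the free pairs among zero neurons.
    zs <- which(qv$q == 0)
    evec <- numeric(n)
    if (length(nz)) {
      mx <- nz[which.max(qv$q[nz])]
      evec[nz] <- d[nz]
      evec[mx] <- -evec[mx]
    }
    idx <- pair_index(n)
    m <- nrow(idx)
    out <- list()
    for (z in zs) {
      dir <- numeric(m)
      sel <- (idx[, 1] %in% nz & idx[, 2] == z) |
        (idx[, 2] %in% nz & idx[, 1] == z)
      other <- ifelse(idx[sel, 1] == z, idx[sel, 2], idx[sel, 1])
      dir[sel] <- evec[other]
      if (any(dir != 0)) out <- c(out, list(dir / sqrt(sum(dir^2))))
    }
    if (length(zs) > 1) {
      zpairs <- which(idx[, 1] %in% zs & idx[, 2] %in% zs)
      for (p in zpairs) {
        dir <- numeric(m); dir[p] <- 1
        out <- c(out, list(dir))
      }
    }
    out
  }
  structure(list(corr = R, case = cs, dimension = dim_, basis = basis,
                 q = qv),
            class = "cancel_solution")
}

#' @export
print.cancel_solution <- function(x, ...) {
  cat("<cancel_solution>", x$case, "case; canceling set dimension",
      x$dimension, "\n")
  invisible(x)
}

.nullspace <- function(C) {
  qrt <- qr(t(C))
  rank <- qrt$rank
  if (rank == ncol(C)) return(matrix(0, ncol(C), 0))
  Q <- qr.Q(qrt, complete = TRUE)
  # with column pivoting the trailing columns span the null space of C
  Q[, (rank + 1):ncol(C), drop = FALSE]
}

.matrix_rank <- function(C, tol = NULL) {
  sv <- svd(C, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(C)) * max(sv, 0) * .Machine$double.eps * 100
  sum(sv > tol)
}

#' Dimension of the set of noise-canceling correlations
#'
#' The convex set of admissible correlation matrices with the canceling
#' property `C^n A = 0` (fixed diagonal).  Strict case: the number of pair
#' unknowns minus the rank of the linear constraint system (for generic
#' all-nonzero `q` this is `N(N-1)/2 - N`); the positive-semidefinite
#' constraint does not cut the dimension further because the strict
#' construction is generic (rank `N-1`).  Equality case: the PSD constraint
#' pins the nonzero block to a unique rank-one matrix and the dimension is
#' `N0(N0+1)/2`, where `N0` is the number of zeros in `q` (the free block of
#' the zero-coordinate neurons plus their coupling to the rank-one
#' direction).
#'
#' @inheritParams info_eval
#' @return integer dimension.
#' @export
canceling_set_dimension <- function(stats) {
  qv <- q_values(stats)
  cs <- cancel_feasibility(qv)
  if (cs == "infeasible") stop("no noise-canceling correlations exist")
  if (cs == "degenerate") stop("zero readout: canceling set undefined")
  n <- stats$n_neurons
  m <- n * (n - 1) / 2
  if (cs == "strict") {
    cm <- .cancel_constraints(qv$A, stats$noise_vars)
    return(as.integer(m - .matrix_rank(cm$C)))
  }
  n0 <- qv$n_zero
  as.integer(n0 * (n0 + 1) / 2)
}

#' Monte-Carlo probability that noise cancellation is feasible
#'
#' Estimates `P(2*max(q) <= sum(q))` for `N` i.i.d. cancellation lengths
#' drawn from `sampler`, with a Wilson score interval.  For large populations
#' this probability approaches one: a single neuron's length must dominate
#' the sum of all others for cancellation to fail.
#'
#' @param n population size.
#' @param reps Monte-Carlo repetitions (>= 1000).
#' @param sampler function of one argument (count) returning nonnegative
#'   draws; default `runif`.
#' @param conf confidence level for the Wilson interval.
#' @param seed optional integer seed.
#' @return list with `estimate`, `lower`, `upper`, `reps`, `n`.
#' @export
feasibility_probability <- function(n, reps = 10000, sampler = stats::runif,
                                    conf = 0.99, seed = NULL) {
  if (reps < 1000) stop("reps must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  block <- 1000L
  done <- 0L
  while (done < reps) {
    b <- min(block, reps - done)
    Q <- matrix(sampler(b * n), nrow = b)
    hits <- hits + sum(2 * apply(Q, 1, max) <= rowSums(Q))
    done <- done + b
  }
  p <- hits / reps
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / reps
  center <- (p + z^2 / (2 * reps)) / den
  half <- z * sqrt(p * (1 - p) / reps + z^2 / (4 * reps^2)) / den
  list(estimate = p, lower = max(0, center - half),
       upper = min(1, center + half), reps = reps, n = n)
}

#' Numerical feasibility of cancellation for general stimulus dimension
#'
#' The polygon condition covers scalar stimuli; for `K > 1` (or as a
#' cross-check) this decides feasibility numerically by alternating
#' projections between the affine set `{rho : C^n A = 0}` and the
#' spectrahedron.  Convergence of the residual to ~0 certifies a canceling
#' point; stalling at a positive residual indicates infeasibility.
#'
#' @inheritParams info_eval
#' @param maxit alternating-projection iterations.
#' @param tol residual tolerance for declaring feasibility.
#' @return list with `feasible`, `corr` (pair vector, valid when feasible),
#'   `residual` (constraint residual norm), `min_eig`.
#' @export
cancel_feasible_numeric <- function(stats, maxit = 300, tol = 1e-7) {
  A <- ole_solution(stats, zero_noise = TRUE)
  cm <- .cancel_constraints(A, stats$noise_vars)
  C <- cm$C; b <- cm$b
  bscale <- max(sqrt(sum(b^2)), 1e-300)
  CCt <- tcrossprod(C) + 1e-12 * diag(nrow(C))
  proj_affine <- function(rho) {
    rho - drop(t(C) %*% solve(CCt, C %*% rho - b))
  }
  m <- ncol(C)
  rho <- rep(0, m)
  res_prev <- Inf
  for (it in seq_len(maxit)) {
    rho <- proj_affine(rho)
    rho <- project_spectrahedron(rho, maxit = 40)
    res <- sqrt(sum((C %*% rho - b)^2)) / bscale
    if (res < tol || abs(res_prev - res) < 1e-12 * max(1, res)) break
    res_prev <- res
  }
  res <- sqrt(sum((C %*% rho - b)^2)) / bscale
  cp <- classify_corr(rho)
  list(feasible = res < tol && cp$admissible, corr = rho, residual = res,
       min_eig = cp$min_eig)
}
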