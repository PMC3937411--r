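# Maximization of an information measure over the spectrahedron of noise
# correlations.  The measures are convex in the correlations, so maximization
# is a (nonconvex) boundary-seeking problem; we use projected multi-start
# gradient ascent with backtracking, with the nearest-correlation-style
# projection of project_spectrahedron() as the feasibility map.  Fisher and
# mutual information diverge as C^n approaches singularity, so for those
# measures the iterates are kept a small eigenvalue floor away from the
# boundary and a solution sitting at the floor is flagged divergent.

.pd_floor_for <- function(measure) {
  if (measure %in% c("fisher", "mutual")) 1e-8 else 0
}

# Feasibility map: spectrahedron projection (with measure-specific PD floor),
# then radial scaling into the norm cap.  Scaling toward the independent point
# preserves admissibility because the set is convex and contains 0.
.feasible_point <- function(rho, pd_floor, norm_cap) {
  rho <- project_spectrahedron(rho, pd_floor = pd_floor, maxit = 25)
  if (!is.null(norm_cap)) {
    nr <- sqrt(sum(rho^2))
    if (nr > norm_cap && nr > 0) rho <- rho * (norm_cap / nr)
  }
  rho
}

#' Maximize an information measure over admissible noise correlations
#'
#' Multi-start projected gradient ascent over the spectrahedron of pairwise
#' correlations, optionally restricted to Euclidean strength `<= norm_cap`.
#' Because the measures are convex in the correlations, any maximizer with
#' information above the independent-noise baseline lies on the boundary of
#' the feasible region (either the positive-semidefinite boundary or the
#' active norm cap); the result records which.  For the Fisher and mutual
#' measures the information diverges as \eqn{C^n} becomes singular; optima
#' reaching the internal eigenvalue floor are reported there with a
#' `divergent` flag rather than as overflow.
#'
#' @inheritParams info_eval
#' @param norm_cap optional nonnegative bound on [correlation_strength()].
#' @param restarts number of optimization starts (independence, a scaled
#'   sign-rule point, random admissible points of mixed rank, plus any
#'   `extra_starts`).
#' @param seed optional integer seed for the random starts.
#' @param tol convergence tolerance on the objective.
#' @param maxit maximum ascent iterations per start.
#' @param penalty quadratic penalty coefficient \eqn{\lambda} (the objective
#'   becomes info \eqn{- \lambda \sum_{i<j} \rho_{ij}^2}); used by
#'   [penalty_sweep()].
#' @param extra_starts optional list of pair vectors to include as starts.
#' @return object of class `optimization_result`: list with `best_corr`,
#'   `best_info` (information at the optimum, excluding any penalty),
#'   `best_objective`, `boundary_flag`, `active_constraint`
#'   (`"psd"`, `"norm_cap"` or `"none"`), `divergent`, `degenerate_flat`,
#'   `n_restarts`, `independent_info`, `trace` (data frame of
#'   iteration/objective for the winning start).
#' @export
maximize_info <- function(stats, measure = c("fisher", "ole", "mutual"),
                          norm_cap = NULL, restarts = 20, seed = NULL,
                          tol = 1e-7, maxit = 150, penalty = 0,
                          extra_starts = NULL) {
  measure <- match.arg(measure)
  if (!is.null(norm_cap) && norm_cap < 0) stop("norm_cap must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- stats$n_neurons
  m <- n * (n - 1) / 2
  floor_ <- .pd_floor_for(measure)

  obj <- function(rho) {
    val <- tryCatch(info_eval(stats, measure, rho), error = function(e) NA_real_)
    if (!is.finite(val)) return(-Inf)
    val - penalty * sum(rho^2)
  }
  grd <- function(rho) {
    g <- tryCatch(info_gradient(stats, measure, rho), error = function(e) NULL)
    if (is.null(g)) return(rep(0, m))
    g - 2 * penalty * rho
  }

  degenerate <- measure == "ole" && !is.null(stats$cross_cov) &&
    all(stats$cross_cov == 0)

  starts <- list(rep(0, m))
  g0 <- grd(rep(0, m))
  if (any(g0 != 0)) {
    dir0 <- g0 / sqrt(sum(g0^2))
    tmax <- tryCatch(max_step(rep(0, m), dir0), error = function(e) 0)
    if (tmax > 0) starts <- c(starts, list(0.9 * tmax * dir0))
  }
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
  while (length(starts) < restarts) {
    d <- sample(max(1, n - 2):n, 1)
    starts <- c(starts, list(random_admissible(n, d)$corr))
  }

  best <- NULL
  for (s in starts) {
    x <- .feasible_point(s, floor_, norm_cap)
    fx <- obj(x)
    if (!is.finite(fx)) next
    step <- 0.1 / max(sqrt(sum(grd(x)^2)), 1e-8)
    tr_it <- c(0); tr_f <- c(fx)
    stall_ref <- fx
    for (it in seq_len(maxit)) {
      g <- grd(x)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) break
      improved <- FALSE
      for (bt in 1:20) {
        y <- .feasible_point(x + step * g, floor_, norm_cap)
        fy <- obj(y)
        if (is.finite(fy) && fy > fx + 1e-13 * max(1, abs(fx))) {
          x <- y; fx <- fy; step <- step * 1.6; improved <- TRUE
          break
        }
        step <- step / 2
      }
      tr_it <- c(tr_it, it); tr_f <- c(tr_f, fx)
      if (!improved || step * gn < tol * 1e-3) break
      if (it %% 15 == 0) {
        if (fx - stall_ref < tol * max(1, abs(fx))) break
        stall_ref <- fx
      }
    }
    if (is.null(best) || fx > best$fx) {
      best <- list(x = x, fx = fx, trace = data.frame(iteration = tr_it,
                                                      objective = tr_f))
    }
  }
  if (is.null(best)) stop("optimization failed from every start")

  x <- best$x
  info_at <- tryCatch(info_eval(stats, measure, x), error = function(e) NA_real_)
  cp <- classify_corr(x)
  ind_info <- tryCatch(info_eval(stats, measure, rep(0, m)),
                       error = function(e) NA_real_)
  cap_active <- !is.null(norm_cap) &&
    abs(sqrt(sum(x^2)) - norm_cap) <= 1e-6 * max(1, norm_cap)
  divergent <- floor_ > 0 && cp$min_eig <= 2 * floor_ &&
    is.finite(info_at) && info_at > ind_info
  active <- if (cap_active) "norm_cap" else if (cp$on_boundary ||
    (floor_ > 0 && cp$min_eig <= 2 * floor_)) "psd" else "none"
  structure(
    list(best_corr = x, best_info = info_at, best_objective = best$fx,
         boundary_flag = active != "none", active_constraint = active,
         divergent = divergent, degenerate_flat = degenerate,
         n_restarts = length(starts), independent_info = ind_info,
         trace = best$trace),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> info =", format(x$best_info, digits = 6),
      " (independent:", format(x$independent_info, digits = 6), ")\n",
      " constraint:", x$active_constraint,
      if (x$divergent) " [divergent measure]" else "",
      if (x$degenerate_flat) " [degenerate flat objective]" else "", "\n")
  invisible(x)
}

#' Penalty coefficient targeting a given correlation strength
#'
#' The Lagrange-multiplier argument for the quadratic penalty shows that near
#' independence the penalized optimum has strength approximately
#' \eqn{\|G\|/(2\lambda)}, where `G` is the gradient at independence.  The
#' coefficient that forces strength `c` is therefore
#' \eqn{\lambda(c) = \|G\|_2 / (2c)} .
#'
#' @inheritParams info_eval
#' @param strength target Euclidean correlation strength `c > 0`.
#' @return scalar penalty coefficient.
#' @export
penalty_for_strength <- function(stats, measure = c("fisher", "ole", "mutual"),
                                 strength) {
  measure <- match.arg(measure)
  if (strength <= 0) stop("strength must be positive")
  g <- info_gradient(stats, measure)
  sqrt(sum(g^2)) / (2 * strength)
}

#' Sweep the penalty coefficient to trace the strength--information frontier
#'
#' For each \eqn{\lambda} (nonincreasing), maximizes
#' info\eqn{{} - \lambda \sum_{i<j} \rho_{ij}^2} over the spectrahedron.  By
#' the Lagrange equivalence each solution is optimal among admissible points
#' whose strength does not exceed its achieved norm, so the resulting
#' (achieved_norm, info) pairs trace the constrained-optimum frontier:
#' achieved norms nonincreasing in \eqn{\lambda}, information nondecreasing
#' as \eqn{\lambda} decreases.  Solutions are warm-started from the previous
#' \eqn{\lambda}.
#'
#' @inheritParams maximize_info
#' @param lambdas nonnegative penalty coefficients, sorted descending (a
#'   geometric grid is a good default); alternatively give
#'   `target_strengths` to build the grid with [penalty_for_strength()].
#' @param target_strengths optional increasing strengths `c` for targeted
#'   penalty coefficients (used if `lambdas` is `NULL`).
#' @param restarts per-lambda optimization starts.
#' @return object of class `penalty_sweep`: list with `frontier` (data frame
#'   `lambda`, `achieved_norm`, `info`) and `corrs` (list of pair vectors).
#' @export
penalty_sweep <- function(stats, measure = c("fisher", "ole", "mutual"),
                          lambdas = NULL, target_strengths = NULL,
                          restarts = 8, seed = NULL, extra_starts = NULL) {
  measure <- match.arg(measure)
  if (is.null(lambdas)) {
    if (is.null(target_strengths)) stop("give lambdas or target_strengths")
    lambdas <- vapply(sort(target_strengths), function(c_)
      penalty_for_strength(stats, measure, c_), numeric(1))
  }
  lambdas <- sort(as.numeric(lambdas), decreasing = TRUE)
  if (any(lambdas < 0)) stop("lambdas must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  prev <- NULL
  rows <- vector("list", length(lambdas))
  corrs <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    es <- extra_starts
    if (!is.null(prev)) es <- c(es, list(prev))
    res <- maximize_info(stats, measure, restarts = restarts,
                         penalty = lambdas[i], extra_starts = es)
    prev <- res$best_corr
    rows[[i]] <- data.frame(lambda = lambdas[i],
                            achieved_norm = correlation_strength(res$best_corr),
                            info = res$best_info)
    corrs[[i]] <- res$best_corr
  }
  structure(list(frontier = do.call(rbind, rows), corrs = corrs,
                 measure = measure),
            class = "penalty_sweep")
}

#' @export
print.penalty_sweep <- function(x, ...) {
  cat("<penalty_sweep>", x$measure, "measure,", nrow(x$frontier), "lambdas\n")
  print(x$frontier)
  invisible(x)
}

#' Information along the sign-rule direction
#'
#' Evaluates the measure along the unit gradient direction at independence
#' (the direction the sign rule prescribes), scaled to each requested
#' strength.  Strengths beyond the maximal admissible step are reported
#' infeasible: the sign-rule direction exits the spectrahedron at a critical
#' length, beyond which no correlation pattern obeying it exists.
#'
#' @inheritParams info_eval
#' @param strengths nonnegative Euclidean strengths to evaluate.
#' @return data frame with columns `strength`, `info` (`NA` when infeasible),
#'   `feasible`; attribute `max_step` holds the critical length.
#' @export
sr_curve <- function(stats, measure = c("fisher", "ole", "mutual"),
                     strengths) {
  measure <- match.arg(measure)
  if (any(strengths < 0)) stop("strengths must be >= 0")
  n <- stats$n_neurons
  m <- n * (n - 1) / 2
  g <- info_gradient(stats, measure)
  gn <- sqrt(sum(g^2))
  if (gn == 0) stop("gradient at independence is zero; sign-rule direction undefined")
  dir <- g / gn
  tmax <- max_step(rep(0, m), dir)
  floor_ <- .pd_floor_for(measure)
  info <- vapply(strengths, function(s) {
    if (s > tmax) return(NA_real_)
    rho <- s * dir
    if (floor_ > 0) rho <- .feasible_point(rho, floor_, NULL)
    out <- tryCatch(info_eval(stats, measure, rho), error = function(e) Inf)
    out
  }, numeric(1))
  structure(data.frame(strength = strengths, info = info,
                       feasible = strengths <= tmax),
            max_step = tmax)
}
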