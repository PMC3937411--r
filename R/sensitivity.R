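# Robustness of the information measures to perturbations of the noise
# covariance or of the tuning statistics, summarized by local condition
# numbers (relative change of the measure per relative change of the input,
# both in spectral norm) and their eigenvalue-based upper bounds.  The bounds
# hold for the Fisher measure with C = C^n and for the OLE measure with C
# replaced by the total covariance C^n + C^mu; because the diagonal of C^mu
# lower-bounds nothing away from zero is needed, the OLE bound stays finite
# even when C^n itself is singular.

#' Condition-number upper bound for an information measure
#'
#' Eigenvalue bound on the local condition number, with
#' \eqn{\lambda_{max}, \lambda_{min}} the extreme eigenvalues of `C`
#' (\eqn{C = C^n} for Fisher, \eqn{C^n + C^\mu} for OLE):
#' \itemize{
#'   \item perturbing the covariance (`target = "noise_cov"`):
#'     \eqn{\kappa \le \lambda_{max}/\lambda_{min}};
#'   \item perturbing the tuning matrix (`target = "cross_cov"`; `L` for OLE,
#'     `f'` for Fisher): \eqn{\kappa \le 2\sqrt{K}\,
#'     (\lambda_{max}/\lambda_{min})\, \|L\|_2 / \min_k \|L_k\|}, with
#'     \eqn{L_k} the k-th column (all assumed nonzero) and `K` the stimulus
#'     dimension.
#' }
#'
#' @inheritParams info_eval
#' @param target `"noise_cov"` (perturb the covariance) or `"cross_cov"`
#'   (perturb `L` / `f'`).
#' @param measure `"fisher"` or `"ole"` (mutual information bounds are not
#'   provided).
#' @return scalar bound.
#' @export
condition_bound <- function(stats, noise = NULL,
                            target = c("noise_cov", "cross_cov"),
                            measure = c("fisher", "ole")) {
  target <- match.arg(target)
  measure <- match.arg(measure)
  noise <- .as_noise(stats, noise)
  C <- if (measure == "fisher") noise$cov else
    noise$cov + .need(stats, "mean_resp_cov")
  er <- .eig_range(C)
  if (er["min"] <= .sing_tol * max(er["max"], 1)) {
    stop("covariance is singular; condition bound undefined")
  }
  ratio <- er[["max"]] / er[["min"]]
  if (target == "noise_cov") return(ratio)
  Lmat <- if (measure == "fisher") .need(stats, "sensitivities") else
    .need(stats, "cross_cov")
  colnorm <- sqrt(colSums(Lmat^2))
  if (any(colnorm == 0)) stop("zero column in tuning matrix; bound undefined")
  2 * sqrt(ncol(Lmat)) * ratio * norm(Lmat, "2") / min(colnorm)
}

#' Empirical local condition number of an information measure
#'
#' Applies a small perturbation to the chosen input and reports the measured
#' ratio of relative information change to relative perturbation size
#' (spectral norms), together with the matching analytic bound.  The
#' perturbation should keep the matrices admissible and be small (relative
#' norm at most ~1e-3) for the local bound to apply.
#'
#' @inheritParams condition_bound
#' @param perturbation matrix added to the target: `N x N` symmetric for
#'   `"noise_cov"`, `N x K` for `"cross_cov"`.
#' @return object of class `sensitivity_report`: list with
#'   `empirical_kappa`, `bound`, `perturb_target`, `perturb_norm`
#'   (relative), `info`, `info_perturbed`.
#' @export
empirical_kappa <- function(stats, noise = NULL, perturbation,
                            target = c("noise_cov", "cross_cov"),
                            measure = c("fisher", "ole")) {
  target <- match.arg(target)
  measure <- match.arg(measure)
  noise <- .as_noise(stats, noise)
  bound <- condition_bound(stats, noise, target, measure)
  i0 <- info_eval(stats, measure, noise)
  if (target == "noise_cov") {
    base_norm <- norm(noise$cov, "2")
    pert <- .sym(as.matrix(perturbation))
    Cn2 <- noise$cov + pert
    noise2 <- structure(list(cov = Cn2, corr = NULL, vars = diag(Cn2)),
                        class = "noise_cov")
    i1 <- info_eval(stats, measure, noise2)
    rel_pert <- norm(pert, "2") / base_norm
  } else {
    field <- if (measure == "fisher") "sensitivities" else "cross_cov"
    Lmat <- .need(stats, field)
    base_norm <- norm(Lmat, "2")
    pert <- as.matrix(perturbation)
    stats2 <- stats
    stats2[[field]] <- Lmat + pert
    i1 <- info_eval(stats2, measure, noise)
    rel_pert <- norm(pert, "2") / base_norm
  }
  emp <- if (rel_pert == 0) 0 else (abs(i1 - i0) / abs(i0)) / rel_pert
  structure(
    list(empirical_kappa = emp, bound = bound, perturb_target = target,
         perturb_norm = rel_pert, info = i0, info_perturbed = i1),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>", x$perturb_target,
      " kappa =", format(x$empirical_kappa, digits = 5),
      " bound =", format(x$bound, digits = 5), "\n")
  invisible(x)
}
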