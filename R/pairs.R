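#' Index table for neuron pairs
#'
#' Pairwise quantities (noise correlations, signal correlations, gradients)
#' are stored as vectors of length `M = N*(N-1)/2` in lexicographic order over
#' pairs `(i, j)` with `i < j`: (1,2), (1,3), ..., (1,N), (2,3), ...
#' This ordering is a package convention; indices are 1-based at the API level.
#'
#' @param n number of neurons.
#' @return integer matrix with `M` rows and columns `i`, `j`.
#' @export
pair_index <- function(n) {
  if (n < 2) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

#' Number of neurons implied by a pair vector
#' @param m length of a pair vector.
#' @return integer `N` with `N*(N-1)/2 == m`.
#' @export
n_from_pairs <- function(m) {
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("length ", m, " is not N*(N-1)/2 for any integer N")
  }
  as.integer(round(n))
}

#' Convert a pair vector of correlations to a correlation matrix
#' @param rho numeric pair vector (length `N*(N-1)/2`).
#' @param n optional number of neurons (inferred from `length(rho)` if absent).
#' @return `n x n` symmetric matrix with unit diagonal.
#' @export
pairvec_to_corrmat <- function(rho, n = NULL) {
  if (is.null(n)) n <- n_from_pairs(length(rho))
  idx <- pair_index(n)
  if (nrow(idx) != length(rho)) stop("pair vector has wrong length for N = ", n)
  R <- diag(1, n)
  R[idx] <- rho
  R[idx[, c(2, 1), drop = FALSE]] <- rho
  R
}

#' Extract the pair vector (upper triangle) of a square symmetric matrix
#' @param R square matrix.
#' @return numeric vector in the package pair order.
#' @export
corrmat_to_pairvec <- function(R) {
  R <- as.matrix(R)
  R[pair_index(nrow(R))]
}
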