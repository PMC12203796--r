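#' Gauss-Hermite quadrature nodes and weights
#'
#' Nodes and weights for \eqn{\int f(x) e^{-x^2} dx \approx \sum_j w_j
#' f(x_j)}, computed by the Golub-Welsch eigenvalue method on the Jacobi
#' matrix of the Hermite recurrence.  Used by [fit_clmm()] for adaptive
#' quadrature over the per-animal random intercept; exposed because the
#' test-suite cross-checks it against closed-form Gaussian moments.
#'
#' @param n number of nodes (>= 1).
#' @return list with `nodes` and `weights`, both length `n`.
#' @examples
#' gh <- gauss_hermite(5)
#' sum(gh$weights * gh$nodes^2) # = sqrt(pi)/2
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  nodes <- e$values[idx]
  weights <- sqrt(pi) * (e$vectors[1, idx])^2
  # enforce exact symmetry of the rule
  nodes <- (nodes - rev(nodes)) / 2
  weights <- (weights + rev(weights)) / 2
  list(nodes = nodes, weights = weights)
}
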