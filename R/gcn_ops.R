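#' Graph degree vector
#'
#' @param A square adjacency matrix (non-negative weights).
#' @return Numeric vector of row sums, `d_i = sum_j A_ij`.
#' @export
degree_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) rlang::abort("A must be square")
  rowSums(A)
}

#' Combinatorial graph Laplacian
#'
#' `L = D - A` with `D` the diagonal degree matrix; rows of `L` sum to zero
#' for symmetric `A`.
#'
#' @param A square adjacency matrix.
#' @return The Laplacian matrix.
#' @export
laplacian <- function(A) {
  d <- degree_matrix(A)
  diag(d, nrow(A)) - A
}

#' Renormalized symmetric propagation operator
#'
#' The graph-convolution propagation operator
#' `S = D~^{-1/2} (A + I) D~^{-1/2}`, where `D~` holds the row sums of
#' `A + I`. Adding the identity (the "renormalization trick") guarantees
#' positive degrees and keeps the spectral radius at most 1, which stabilizes
#' stacked graph convolutions.
#'
#' @param A square non-negative adjacency matrix, or a `vnfc_graph`.
#' @return Symmetric m x m operator matrix.
#' @examples
#' renormalized_operator(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
#' @export
renormalized_operator <- function(A) {
  if (inherits(A, "vnfc_graph")) A <- A$adjacency
  if (!is.matrix(A) || nrow(A) != ncol(A)) rlang::abort("A must be square")
  if (any(A < 0)) rlang::abort("adjacency must be non-negative")
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  At / sqrt(outer(d, d))   # S_ij = At_ij / sqrt(d_i d_j), exactly symmetric
}
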