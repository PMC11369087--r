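#' Texture statistics of a co-occurrence matrix
#'
#' The five gray-level co-occurrence (GLCM-style) discriminant statistics of
#' a normalized k x k co-occurrence matrix G, with `i`, `j` the 1-based
#' row/column indices:
#' \itemize{
#'   \item energy: `sum(G^2)` - overall intensity of pair interactions
#'   \item entropy: `-sum(G * log2(G + eps))` in bits - randomness of the
#'     pair distribution; `eps` avoids `log(0)` and is negligible against
#'     the smallest nonzero normalized count
#'   \item homogeneity: `sum(G / (1 + (i - j)^2))` - concentration near the
#'     diagonal
#'   \item contrast: `sum((i - j)^2 * G)`
#'   \item dissimilarity: `sum(abs(i - j) * G)`
#' }
#' An all-zero matrix (no pairs) yields all-zero statistics.
#'
#' @param matrix a `cooc_matrix` (normalized or all-zero).
#' @param eps additive constant inside the entropy logarithm.
#' @return named numeric vector `c(energy, entropy, homogeneity, contrast,
#'   dissimilarity)`.
#' @examples
#' rs <- reduce_sequence("ACACAC", load_alphabet("no_reduction"))
#' texture_features(cooccurrence_matrix(rs, 1))
#' @export
texture_features <- function(matrix, eps = 1e-12) {
  stopifnot(inherits(matrix, "cooc_matrix"))
  G <- unclass(matrix)
  k <- nrow(G)
  i <- row(G)
  j <- col(G)
  c(energy        = sum(G^2),
    entropy       = -sum(G * log2(G + eps)),
    homogeneity   = sum(G / (1 + (i - j)^2)),
    contrast      = sum((i - j)^2 * G),
    dissimilarity = sum(abs(i - j) * G))
}

TEXTURE_STATS <- c("energy", "entropy", "homogeneity", "contrast", "dissimilarity")
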