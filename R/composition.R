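#' Normalized monogram (single-symbol) composition
#'
#' Counts each alphabet symbol in the encoded sequence and divides by the
#' sequence length, giving the standard amino-acid (or reduced-group)
#' composition vector. Entries follow `alphabet$symbols` order and sum to 1.
#'
#' @param rep_seq a `rep_seq` from [reduce_sequence()].
#' @return named numeric vector of length `k` (alphabet size).
#' @examples
#' rs <- reduce_sequence("AAC", load_alphabet("no_reduction"))
#' monogram_counts(rs)[c("A", "C")]
#' @export
monogram_counts <- function(rep_seq) {
  stopifnot(inherits(rep_seq, "rep_seq"))
  n <- length(rep_seq$tokens)
  if (n == 0L) stop("cannot normalize monogram counts of an empty sequence",
                    call. = FALSE)
  symbols <- rep_seq$alphabet$symbols
  counts <- table(factor(rep_seq$tokens, levels = symbols))
  stats::setNames(as.numeric(counts) / n, symbols)
}

#' Offset co-occurrence (bigram) matrix
#'
#' Counts ordered symbol pairs `(a_t, a_{t+delta})` over positions
#' `t = 1 .. n - delta` and normalizes by the pair count `n - delta`, so
#' nonempty matrices sum to 1. `delta = 1` is the adjacent-bigram
#' (dipeptide-composition) matrix. When `delta >= n` there are no pairs and
#' the all-zero matrix is returned, keeping feature width constant across a
#' dataset of mixed lengths.
#'
#' @param rep_seq a `rep_seq`.
#' @param offset positive integer gap `delta` between pair members.
#' @return a `cooc_matrix`: k x k numeric matrix (dimnames = symbols, row =
#'   first pair member) with attributes `offset` and `pair_count`.
#' @examples
#' rs <- reduce_sequence("ACAC", load_alphabet("no_reduction"))
#' m <- cooccurrence_matrix(rs, 1)
#' m["A", "C"]
#' @export
cooccurrence_matrix <- function(rep_seq, offset = 1L) {
  stopifnot(inherits(rep_seq, "rep_seq"))
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset) || offset < 1L)
    stop("offset must be a positive integer", call. = FALSE)
  symbols <- rep_seq$alphabet$symbols
  k <- length(symbols)
  n <- length(rep_seq$tokens)
  n_pairs <- max(0L, n - offset)
  G <- matrix(0, k, k, dimnames = list(symbols, symbols))
  if (n_pairs > 0L) {
    first <- factor(rep_seq$tokens[seq_len(n_pairs)], levels = symbols)
    second <- factor(rep_seq$tokens[seq_len(n_pairs) + offset], levels = symbols)
    G <- unclass(table(first, second)) / n_pairs
    dimnames(G) <- list(symbols, symbols)
  }
  structure(G, offset = offset, pair_count = n_pairs, class = c("cooc_matrix", "matrix"))
}

#' Flatten a co-occurrence matrix into a bigram feature vector
#'
#' Row-major flattening `(G_11, G_12, ..., G_1k, G_21, ..., G_kk)`; element
#' order is fixed by the alphabet symbol order, names are `"AB(delta)"` where
#' `A` is the row (first) symbol and `B` the column symbol.
#'
#' @param matrix a `cooc_matrix`.
#' @return named numeric vector of length k^2.
#' @export
bigram_vector <- function(matrix) {
  stopifnot(inherits(matrix, "cooc_matrix"))
  symbols <- rownames(matrix)
  delta <- attr(matrix, "offset")
  nms <- as.vector(t(outer(symbols, symbols,
                           function(a, b) paste0(a, b, "(", delta, ")"))))
  # t() because R vectorizes column-major; we flatten row-major
  stats::setNames(as.numeric(t(unclass(matrix))), nms)
}
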