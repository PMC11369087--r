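#' Build a shifted non-overlapping n-gram corpus
#'
#' Training documents for sequence embeddings: each encoded sequence is
#' split into `ngram_size` documents, one per shift offset `0 ..
#' ngram_size - 1`, each consisting of the consecutive non-overlapping
#' n-grams starting at that shift. Trailing residues shorter than `n` are
#' dropped. Sequences shorter than `ngram_size` contribute no documents
#' (with a warning).
#'
#' @param sequences list of `rep_seq` objects sharing one alphabet.
#' @param ngram_size word length `n` (default 3, the ProtVec convention).
#' @return an `ngram_corpus`: list with `docs` (list of character vectors),
#'   `alphabet`, `ngram_size`.
#' @export
build_corpus <- function(sequences, ngram_size = 3L) {
  ngram_size <- as.integer(ngram_size)
  stopifnot(ngram_size >= 1L, length(sequences) > 0L)
  stopifnot(all(vapply(sequences, inherits, logical(1), "rep_seq")))
  alphabet <- sequences[[1]]$alphabet
  docs <- list()
  n_short <- 0L
  for (rs in sequences) {
    n <- length(rs$tokens)
    if (n < ngram_size) { n_short <- n_short + 1L; next }
    for (shift in 0:(ngram_size - 1L)) {
      starts <- seq.int(1L + shift, n - ngram_size + 1L, by = ngram_size)
      if (!length(starts) || starts[1] > n - ngram_size + 1L) next
      words <- vapply(starts, function(s)
        paste(rs$tokens[s:(s + ngram_size - 1L)], collapse = ""), character(1))
      docs[[length(docs) + 1L]] <- words
    }
  }
  if (n_short > 0L)
    warning(n_short, " sequence(s) shorter than ngram_size contributed no documents")
  structure(list(docs = docs, alphabet = alphabet, ngram_size = ngram_size),
            class = "ngram_corpus")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a skip-gram n-gram embedding model
#'
#' Fits word2vec-style skip-gram embeddings with negative sampling to an
#' n-gram corpus: each n-gram word predicts its context words within
#' `window` positions through a single hidden layer; negatives are drawn
#' from the unigram distribution raised to 3/4. Training is plain
#' single-threaded stochastic gradient descent, so results are fully
#' deterministic for a given seed. Geared to the corpus sizes of peptide
#' datasets (hundreds of 31-mers), not web-scale text.
#'
#' @param corpus an `ngram_corpus` from [build_corpus()].
#' @param dimension embedding length; defaults to 50 on the standard
#'   alphabet and 300 on reduced alphabets (the ProtVec / RA2Vec defaults).
#' @param window context half-width in words.
#' @param epochs passes over the corpus.
#' @param seed RNG seed for initialization and negative sampling.
#' @param min_count drop n-grams seen fewer times (default 1: tiny corpora
#'   stay fully covered).
#' @param learning_rate initial SGD step size, linearly decayed per epoch.
#' @param negative number of negative samples per positive pair.
#' @return an `embedding_model`: list with `alphabet`, `ngram_size`,
#'   `dimension`, `vectors` (vocabulary x dimension matrix, rownames =
#'   n-grams) and `meta`.
#' @export
train_embedding <- function(corpus, dimension = NULL, window = 5L,
                            epochs = 10L, seed = 1L, min_count = 1L,
                            learning_rate = 0.025, negative = 5L) {
  stopifnot(inherits(corpus, "ngram_corpus"))
  if (!length(corpus$docs)) stop("empty corpus", call. = FALSE)
  if (is.null(dimension)) dimension <- default_embedding_dim(corpus$alphabet)
  dimension <- as.integer(dimension)

  counts <- table(unlist(corpus$docs, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (!length(counts)) stop("no n-gram reaches min_count", call. = FALSE)
  # deterministic vocabulary order: frequency-descending, ties lexicographic
  vocab <- names(counts)[order(-as.integer(counts), names(counts), method = "radix")]
  V <- length(vocab)
  idx <- stats::setNames(seq_len(V), vocab)
  freq <- as.numeric(counts[vocab])
  neg_prob <- freq^0.75 / sum(freq^0.75)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  W_in <- matrix(stats::runif(V * dimension, -0.5, 0.5) / dimension, V, dimension)
  W_out <- matrix(0, V, dimension)

  docs <- lapply(corpus$docs, function(d) unname(idx[d[d %in% vocab]]))
  docs <- docs[lengths(docs) > 0L]
  for (epoch in seq_len(epochs)) {
    lr <- learning_rate * max(1 - (epoch - 1) / epochs, 0.05)
    for (doc in docs) {
      L <- length(doc)
      for (t in seq_len(L)) {
        ctx <- doc[max(1L, t - window):min(L, t + window)][-(t - max(1L, t - window) + 1L)]
        if (!length(ctx)) next
        w <- doc[t]
        for (c_pos in ctx) {
          targets <- c(c_pos, sample.int(V, negative, replace = TRUE, prob = neg_prob))
          labels <- c(1, numeric(negative))
          vin <- W_in[w, ]
          g <- lr * (labels - sigmoid(W_out[targets, , drop = FALSE] %*% vin))
          W_in[w, ] <- vin + crossprod(W_out[targets, , drop = FALSE], g)
          W_out[targets, ] <- W_out[targets, ] + tcrossprod(g, vin)
        }
      }
    }
  }
  rownames(W_in) <- vocab
  structure(list(alphabet = corpus$alphabet, ngram_size = corpus$ngram_size,
                 dimension = dimension, vectors = W_in,
                 meta = list(window = window, epochs = epochs, seed = seed,
                             min_count = min_count, n_docs = length(docs))),
            class = "embedding_model")
}

#' Default embedding dimension for an alphabet
#'
#' 50 on the standard 20-letter alphabet (ProtVec convention), 300 on
#' reduced alphabets (RA2Vec convention).
#'
#' @param alphabet an `aa_alphabet` or alphabet name.
#' @return integer dimension.
#' @export
default_embedding_dim <- function(alphabet) {
  name <- if (inherits(alphabet, "aa_alphabet")) alphabet$name else alphabet
  if (identical(name, "no_reduction")) 50L else 300L
}

#' Embed a sequence as the sum of its overlapping n-gram vectors
#'
#' All overlapping n-gram windows (stride 1) of the encoded sequence are
#' looked up in the model vocabulary and summed. Out-of-vocabulary n-grams
#' contribute the zero vector; their count is attached as attribute `n_oov`.
#'
#' @param rep_seq a `rep_seq` on the model's alphabet.
#' @param model an `embedding_model`.
#' @return numeric vector of length `model$dimension`.
#' @export
embed_sequence <- function(rep_seq, model) {
  stopifnot(inherits(rep_seq, "rep_seq"), inherits(model, "embedding_model"))
  if (!identical(rep_seq$alphabet$name, model$alphabet$name))
    stop("alphabet mismatch: sequence is '", rep_seq$alphabet$name,
         "', model is '", model$alphabet$name, "'", call. = FALSE)
  n <- length(rep_seq$tokens)
  ng <- model$ngram_size
  out <- numeric(model$dimension)
  n_oov <- 0L
  if (n >= ng) {
    for (s in seq_len(n - ng + 1L)) {
      word <- paste(rep_seq$tokens[s:(s + ng - 1L)], collapse = "")
      if (word %in% rownames(model$vectors)) {
        out <- out + model$vectors[word, ]
      } else n_oov <- n_oov + 1L
    }
  }
  attr(out, "n_oov") <- n_oov
  out
}

#' Write / read embedding vectors in word2vec text format
#'
#' Header line `"<vocab_size> <dimension>"`, then one line per n-gram:
#' the token followed by its vector components, space-separated.
#'
#' @param model an `embedding_model`.
#' @param path output file.
#' @export
write_word2vec <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(model$vectors), model$dimension), con)
  for (i in seq_len(nrow(model$vectors)))
    writeLines(paste(rownames(model$vectors)[i],
                     paste(format(model$vectors[i, ], digits = 17, scientific = TRUE,
                                  trim = TRUE), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_word2vec
#' @param alphabet,ngram_size metadata to attach to the loaded model
#'   (the text format itself stores only tokens and vectors).
#' @export
read_word2vec <- function(path, alphabet, ngram_size = 3L) {
  if (is.character(alphabet)) alphabet <- load_alphabet(alphabet)
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(vecs) <- vocab
  if (nrow(vecs) != hdr[1]) stop("vector count does not match header", call. = FALSE)
  structure(list(alphabet = alphabet, ngram_size = as.integer(ngram_size),
                 dimension = hdr[2], vectors = vecs,
                 meta = list(source = path)),
            class = "embedding_model")
}
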