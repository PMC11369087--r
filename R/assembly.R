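FEATURE_TYPES <- c("counts", "mat", "tfeat", "pro2vec")

#' Define a feature-extraction configuration
#'
#' The framework is parameterized by three lists: sequence representations
#' (alphabet names), feature families, and co-occurrence offsets. The
#' families are `"counts"` (normalized monogram composition, k values per
#' representation), `"mat"` (flattened normalized delta-offset bigram
#' matrix, k^2 values per representation per offset), `"tfeat"` (five
#' texture statistics per representation per offset) and `"pro2vec"`
#' (skip-gram sequence embedding, one block per representation; dimension
#' 50 for the standard alphabet, 300 for reduced ones by default).
#' `counts` and `pro2vec` do not depend on the offsets.
#'
#' Feature families are always assembled in the canonical order counts,
#' mat, tfeat, pro2vec within each representation; representations and
#' offsets keep the order given.
#'
#' @param representations character vector of alphabet names (or a list of
#'   `aa_alphabet` objects), no duplicates.
#' @param feature_types subset of `c("counts", "mat", "tfeat", "pro2vec")`.
#' @param offsets positive integer offsets (deltas), no duplicates.
#' @param embedding_config optional named list (by representation) of
#'   lists with `ngram_size` and `dimension`, used when `"pro2vec"` is
#'   selected; missing entries fall back to `ngram_size = 3` and the
#'   default dimension for the alphabet.
#' @return a `feature_spec` object.
#' @examples
#' spec <- feature_spec(c("no_reduction", "hydro"), c("counts", "tfeat"), c(1, 3))
#' feature_dimension(spec)  # 45
#' @export
feature_spec <- function(representations, feature_types, offsets = 1L,
                         embedding_config = NULL) {
  if (is.character(representations)) {
    if (anyDuplicated(representations))
      stop("duplicate representations", call. = FALSE)
    alphabets <- lapply(representations, load_alphabet)
  } else {
    alphabets <- representations
    stopifnot(all(vapply(alphabets, inherits, logical(1), "aa_alphabet")))
  }
  names(alphabets) <- vapply(alphabets, `[[`, character(1), "name")
  if (anyDuplicated(names(alphabets)))
    stop("duplicate representations", call. = FALSE)
  bad <- setdiff(feature_types, FEATURE_TYPES)
  if (length(bad))
    stop("unknown feature type(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(FEATURE_TYPES, collapse = ", "), call. = FALSE)
  if (anyDuplicated(feature_types)) stop("duplicate feature types", call. = FALSE)
  feature_types <- FEATURE_TYPES[FEATURE_TYPES %in% feature_types]
  offsets <- as.integer(offsets)
  if (anyDuplicated(offsets)) stop("duplicate offsets", call. = FALSE)
  if (any(offsets < 1L)) stop("offsets must be positive", call. = FALSE)

  emb <- NULL
  if ("pro2vec" %in% feature_types) {
    emb <- lapply(names(alphabets), function(nm) {
      user <- if (!is.null(embedding_config)) embedding_config[[nm]]
      list(ngram_size = if (!is.null(user$ngram_size)) as.integer(user$ngram_size) else 3L,
           dimension = if (!is.null(user$dimension)) as.integer(user$dimension)
                       else default_embedding_dim(alphabets[[nm]]))
    })
    names(emb) <- names(alphabets)
  }
  structure(list(alphabets = alphabets, feature_types = feature_types,
                 offsets = offsets, embedding_config = emb),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec>\n",
      " representations:", paste(names(x$alphabets), collapse = ", "), "\n",
      " feature types:  ", paste(x$feature_types, collapse = ", "), "\n",
      " offsets:        ", paste(x$offsets, collapse = ", "), "\n",
      " dimension:      ", feature_dimension(x), "\n")
  invisible(x)
}

#' Closed-form width of the assembled feature vector
#'
#' Sums, over representations of alphabet size k: k for `counts`, k^2 per
#' offset for `mat`, 5 per offset for `tfeat`, and the embedding dimension
#' for `pro2vec`.
#'
#' @param spec a `feature_spec`.
#' @return integer feature count; always equals
#'   `length(feature_names(spec))`.
#' @export
feature_dimension <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  ft <- spec$feature_types
  n_off <- length(spec$offsets)
  total <- 0L
  for (nm in names(spec$alphabets)) {
    k <- length(spec$alphabets[[nm]]$symbols)
    if ("counts" %in% ft) total <- total + k
    if ("mat" %in% ft) total <- total + k^2 * n_off
    if ("tfeat" %in% ft) total <- total + 5L * n_off
    if ("pro2vec" %in% ft) total <- total + spec$embedding_config[[nm]]$dimension
  }
  as.integer(total)
}

#' Canonical feature names for a configuration
#'
#' Deterministic naming: monograms are the bare symbol (`"K"`, `"H_2"`),
#' bigrams `"AB(delta)"` with A the first pair member (`"H_2H_2(1)"`),
#' texture statistics `"<rep>:<stat>(delta)"`, embedding components
#' `"<rep>:p2v_<i>"`. Order is representation-major, then family in
#' canonical order, then offset, then within-block index. Reduced-group
#' labels carry their `H_`/`C_` prefixes so names never collide across
#' representations.
#'
#' @param spec a `feature_spec`.
#' @return character vector of length `feature_dimension(spec)`.
#' @export
feature_names <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  out <- character(0)
  for (nm in names(spec$alphabets)) {
    syms <- spec$alphabets[[nm]]$symbols
    for (ft in spec$feature_types) {
      if (ft == "counts") out <- c(out, syms)
      if (ft == "mat")
        for (d in spec$offsets)
          out <- c(out, as.vector(t(outer(syms, syms,
                   function(a, b) paste0(a, b, "(", d, ")")))))
      if (ft == "tfeat")
        for (d in spec$offsets)
          out <- c(out, paste0(nm, ":", TEXTURE_STATS, "(", d, ")"))
      if (ft == "pro2vec")
        out <- c(out, paste0(nm, ":p2v_",
                             seq_len(spec$embedding_config[[nm]]$dimension)))
    }
  }
  if (anyDuplicated(out))
    stop("feature name collision across representations", call. = FALSE)
  out
}

#' Train embedding models required by a configuration
#'
#' One skip-gram model per representation selecting `"pro2vec"`, trained on
#' the supplied sequences (typically the training split only, to avoid
#' information leakage into held-out folds).
#'
#' @param sequences character vector of amino-acid sequences.
#' @param spec a `feature_spec` with `"pro2vec"` selected.
#' @param seed,window,epochs passed to [train_embedding()].
#' @return named list of `embedding_model`s keyed by representation.
#' @export
train_spec_embeddings <- function(sequences, spec, seed = 1L, window = 5L,
                                  epochs = 10L) {
  stopifnot(inherits(spec, "feature_spec"))
  if (!("pro2vec" %in% spec$feature_types)) return(NULL)
  models <- list()
  for (nm in names(spec$alphabets)) {
    cfg <- spec$embedding_config[[nm]]
    reps <- lapply(sequences, reduce_sequence, alphabet = spec$alphabets[[nm]])
    corpus <- build_corpus(reps, cfg$ngram_size)
    models[[nm]] <- train_embedding(corpus, dimension = cfg$dimension,
                                    window = window, epochs = epochs,
                                    seed = seed)
  }
  models
}

#' Extract the named feature vector of one sequence
#'
#' For each representation independently: encode the sequence, then compute
#' each selected family (monogram counts once; bigram matrix and texture
#' statistics once per offset; embedding once) and concatenate all blocks
#' in [feature_names()] order.
#'
#' @param sequence amino-acid string.
#' @param spec a `feature_spec`.
#' @param models named list of `embedding_model`s (required when
#'   `"pro2vec"` is selected), e.g. from [train_spec_embeddings()].
#' @return named numeric vector of length `feature_dimension(spec)`.
#' @export
extract_features <- function(sequence, spec, models = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  out <- numeric(0)
  for (nm in names(spec$alphabets)) {
    rs <- reduce_sequence(sequence, spec$alphabets[[nm]])
    mats <- NULL
    if (any(c("mat", "tfeat") %in% spec$feature_types))
      mats <- lapply(spec$offsets, function(d) cooccurrence_matrix(rs, d))
    for (ft in spec$feature_types) {
      if (ft == "counts") out <- c(out, monogram_counts(rs))
      if (ft == "mat")
        for (m in mats) out <- c(out, bigram_vector(m))
      if (ft == "tfeat")
        for (i in seq_along(mats)) {
          tf <- texture_features(mats[[i]])
          names(tf) <- paste0(nm, ":", TEXTURE_STATS, "(", spec$offsets[i], ")")
          out <- c(out, tf)
        }
      if (ft == "pro2vec") {
        if (is.null(models) || is.null(models[[nm]]))
          stop("pro2vec selected but no embedding model supplied for '",
               nm, "'", call. = FALSE)
        v <- as.numeric(embed_sequence(rs, models[[nm]]))
        names(v) <- paste0(nm, ":p2v_", seq_along(v))
        out <- c(out, v)
      }
    }
  }
  out
}

#' Extract the feature matrix of a peptide dataset
#'
#' @param peptides peptide data.frame (`id`, `sequence`, optional `label`).
#' @param spec a `feature_spec`.
#' @param models embedding models, as in [extract_features()].
#' @return a `feature_matrix`: list with `x` (numeric matrix, rows in
#'   dataset order, rownames = ids, colnames = feature names), `labels`
#'   (or NULL) and `spec`.
#' @export
extract_matrix <- function(peptides, spec, models = NULL) {
  stopifnot(inherits(spec, "feature_spec"), nrow(peptides) > 0L)
  nms <- feature_names(spec)
  x <- matrix(NA_real_, nrow(peptides), length(nms),
              dimnames = list(peptides$id, nms))
  for (i in seq_len(nrow(peptides))) {
    v <- tryCatch(extract_features(peptides$sequence[i], spec, models),
                  error = function(e)
                    stop("feature extraction failed for '", peptides$id[i],
                         "': ", conditionMessage(e), call. = FALSE))
    x[i, ] <- v
  }
  structure(list(x = x,
                 labels = if ("label" %in% names(peptides)) peptides$label,
                 spec = spec),
            class = "feature_matrix")
}

#' Write a feature matrix as CSV
#'
#' Header = feature names, first column the row id, last column the label
#' when present.
#'
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = rownames(fm$x), fm$x, check.names = FALSE)
  if (!is.null(fm$labels)) df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
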