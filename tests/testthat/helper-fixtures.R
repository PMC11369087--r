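# Shared fixture builders; everything is generated in code at test time.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# independent of reduce_sequence: per-character lookup loop
brute_reduce <- function(sequence, mapping) {
  chars <- strsplit(sequence, "")[[1]]
  vapply(chars, function(ch) mapping[[ch]], character(1), USE.NAMES = FALSE)
}

# brute-force pair tally: double loop over positions, no factor/table tricks
brute_cooc <- function(tokens, symbols, delta) {
  G <- matrix(0, length(symbols), length(symbols),
              dimnames = list(symbols, symbols))
  n <- length(tokens)
  if (n > delta) {
    for (t in seq_len(n - delta))
      G[tokens[t], tokens[t + delta]] <- G[tokens[t], tokens[t + delta]] + 1
  }
  G
}

tiny_alphabet <- function(symbols = c("A", "B")) {
  # maps the 20 amino acids onto a small symbol set round-robin; used to
  # exercise composition/texture code on low-k alphabets
  mapping <- stats::setNames(rep_len(symbols, 20), AA)
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(paste(names(mapping), mapping, sep = "\t"), path)
  load_alphabet(path)
}

# independent Shapley oracle: average marginal contribution over every
# feature ordering (the permutation form of the subset-weighted sum)
permutation_shapley_oracle <- function(model_fn, x, background) {
  x <- unlist(x)
  d <- length(x)
  v <- function(members) {
    z <- as.matrix(background)
    if (length(members)) z[, members] <- rep(x[members], each = nrow(z))
    mean(model_fn(z))
  }
  phi <- numeric(d)
  perms <- all_permutations(d)
  for (r in seq_len(nrow(perms))) {
    prev <- v(integer(0))
    for (pos in seq_len(d)) {
      cur <- v(perms[r, seq_len(pos)])
      i <- perms[r, pos]
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  stats::setNames(phi / nrow(perms), names(x))
}

all_permutations <- function(d) {
  if (d == 1) return(matrix(1L))
  sub <- all_permutations(d - 1)
  do.call(rbind, lapply(seq_len(d), function(i) {
    rest <- setdiff(seq_len(d), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

rep_from_tokens <- function(tokens, alphabet) {
  # build a rep_seq directly from tokens (bypasses amino-acid validation,
  # for composition-layer tests on abstract symbol sequences)
  structure(list(alphabet = alphabet, tokens = tokens, source_id = "toy"),
            class = "rep_seq")
}
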