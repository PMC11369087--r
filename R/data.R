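# Approximate background amino-acid frequencies in vertebrate proteomes
# (Swiss-Prot composition statistics, rounded); used as the default
# residue distribution of the synthetic generator.
BACKGROUND_AA_FREQ <- c(
  A = 0.0826, C = 0.0139, D = 0.0546, E = 0.0672, F = 0.0387,
  G = 0.0707, H = 0.0228, I = 0.0591, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292)

#' Read peptide records from FASTA or CSV
#'
#' A peptide record is an id, an amino-acid sequence and a binary label
#' (1 = modified site). CSV files need columns `id`, `sequence`, `label`.
#' FASTA description lines carry the label as a `label=0` / `label=1`
#' token. Sequences are uppercased on load.
#'
#' @param path input file.
#' @param format `"fasta"` or `"csv"`; guessed from the extension when
#'   missing.
#' @return data.frame with columns `id`, `sequence`, `label`,
#'   `center_residue` (the middle residue for odd-length peptides).
#' @export
read_peptides <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa")) "fasta" else "csv"
  }
  if (format == "fasta") {
    aas <- Biostrings::readAAStringSet(path)
    desc <- names(aas)
    id <- vapply(strsplit(desc, "\\s+"), `[[`, character(1), 1L)
    lab <- regmatches(desc, regexpr("label=[01]", desc))
    label <- rep(NA_integer_, length(desc))
    has <- grepl("label=[01]", desc)
    label[has] <- as.integer(sub("label=", "", lab))
    seqs <- toupper(as.character(aas))
  } else {
    tab <- utils::read.csv(path, colClasses = "character")
    need <- c("id", "sequence", "label")
    if (!all(need %in% names(tab)))
      stop("csv must have columns id, sequence, label", call. = FALSE)
    id <- tab$id
    seqs <- toupper(tab$sequence)
    label <- as.integer(tab$label)
  }
  peptide_frame(id, seqs, label)
}

peptide_frame <- function(id, sequence, label) {
  center <- vapply(sequence, function(s) {
    n <- nchar(s)
    if (n %% 2L == 1L) substr(s, (n + 1L) %/% 2L, (n + 1L) %/% 2L) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  data.frame(id = as.character(id), sequence = unname(sequence),
             label = label, center_residue = center,
             stringsAsFactors = FALSE)
}

#' Write peptide records to FASTA or CSV
#'
#' @param peptides data.frame with `id`, `sequence`, `label`.
#' @inheritParams read_peptides
#' @export
write_peptides <- function(peptides, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa")) "fasta" else "csv"
  }
  if (format == "fasta") {
    lines <- character(0)
    for (i in seq_len(nrow(peptides)))
      lines <- c(lines,
                 paste0(">", peptides$id[i], " label=", peptides$label[i]),
                 peptides$sequence[i])
    writeLines(lines, path)
  } else {
    utils::write.csv(peptides[, c("id", "sequence", "label")], path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Extract a fixed flanking window around a modification site
#'
#' Returns the `2 * flank + 1`-residue peptide centred on the site
#' (15 residues upstream and downstream by default, giving 31-mers).
#' Sites closer than `flank` to either protein terminus are rejected
#' rather than padded, matching a dataset from which padded windows have
#' been removed.
#'
#' @param protein full-length amino-acid string.
#' @param site_pos 1-based position of the site residue.
#' @param flank residues kept on each side (default 15).
#' @param id identifier for the resulting record.
#' @param label optional 0/1 label.
#' @return one-row peptide data.frame (see [read_peptides()]).
#' @export
extract_window <- function(protein, site_pos, flank = 15L, id = NA_character_,
                           label = NA_integer_) {
  n <- nchar(protein)
  site_pos <- as.integer(site_pos)
  if (site_pos < 1L || site_pos > n)
    stop("site_pos ", site_pos, " outside protein of length ", n, call. = FALSE)
  if (site_pos - flank < 1L)
    stop("site rejected: only ", site_pos - 1L, " upstream residues, need ",
         flank, call. = FALSE)
  if (site_pos + flank > n)
    stop("site rejected: only ", n - site_pos, " downstream residues, need ",
         flank, call. = FALSE)
  peptide_frame(id, toupper(substr(protein, site_pos - flank, site_pos + flank)),
                label)
}

#' Drop records containing the padding residue X
#'
#' @param peptides peptide data.frame.
#' @return list with `kept` (unaltered surviving records) and `dropped`
#'   (integer count removed).
#' @export
filter_padded <- function(peptides) {
  has_x <- grepl("X", peptides$sequence, fixed = TRUE)
  if (all(has_x) && nrow(peptides) > 0L)
    warning("all records contained 'X'; nothing kept")
  list(kept = peptides[!has_x, , drop = FALSE], dropped = sum(has_x))
}

#' Generate a synthetic peptide-window dataset
#'
#' Emulates the shape of a curated AMPylation-site dataset: fixed-length
#' windows (31-mers by default) with a binary label. Negatives are drawn
#' i.i.d. from background amino-acid frequencies. Positives may differ in
#' two configurable ways: their centre residue is sampled from the typical
#' modification targets T/Y (on by default), and a per-residue log-odds
#' tilt (`composition_shift`) can be applied to the background to plant a
#' compositional signal. An optional exact `motif` string can be embedded
#' at a fixed position in positives.
#'
#' @param n_pos,n_neg class sizes (the study scale is 153 / 250).
#' @param length window length (odd; default 31).
#' @param composition_shift named numeric vector of per-residue log-odds
#'   added to the log background frequencies of positives (e.g.
#'   `c(K = 2)` enriches lysine about e^2-fold before renormalization).
#' @param motif optional list `list(pattern =, at =)` planted in positives.
#' @param center_ty sample the positive centre residue from `c("T","Y")`.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return peptide data.frame of `n_pos + n_neg` rows (positives first).
#' @export
generate_synthetic <- function(n_pos, n_neg, length = 31L,
                               composition_shift = NULL, motif = NULL,
                               center_ty = TRUE, seed = 1L) {
  stopifnot(n_pos >= 0L, n_neg >= 0L, length >= 1L)
  if (!is.null(composition_shift)) {
    if (is.null(names(composition_shift)) ||
        !all(names(composition_shift) %in% AA20))
      stop("composition_shift must be named by standard amino acids",
           call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  pos_freq <- BACKGROUND_AA_FREQ
  if (!is.null(composition_shift)) {
    lo <- log(pos_freq)
    lo[names(composition_shift)] <- lo[names(composition_shift)] + composition_shift
    pos_freq <- exp(lo) / sum(exp(lo))
  }
  draw <- function(freq, len) paste(sample(names(freq), len, replace = TRUE,
                                           prob = freq), collapse = "")
  centre <- (length + 1L) %/% 2L
  make_pos <- function(i) {
    s <- draw(pos_freq, length)
    if (center_ty && length %% 2L == 1L)
      substr(s, centre, centre) <- sample(c("T", "Y"), 1L)
    if (!is.null(motif))
      substr(s, motif$at, motif$at + nchar(motif$pattern) - 1L) <- motif$pattern
    s
  }
  pos <- vapply(seq_len(n_pos), make_pos, character(1))
  neg <- vapply(seq_len(n_neg), function(i) draw(BACKGROUND_AA_FREQ, length),
                character(1))
  peptide_frame(
    id = c(sprintf("pos_%03d", seq_len(n_pos)), sprintf("neg_%03d", seq_len(n_neg))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(n_pos, n_neg)))
}
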