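#' @keywords internal
"_PACKAGE"

# The 20 standard amino acids, fixed ordering used throughout.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Sequence representation alphabets
#'
#' An alphabet is a named, ordered symbol set together with a total mapping
#' from the 20 standard amino acids onto those symbols. The identity alphabet
#' (`"no_reduction"`, 20 symbols) keeps the raw sequence; the two packaged
#' reduced alphabets collapse residues into 5 hydropathy groups
#' (`"hydro"`, labels `H_1`..`H_5` ordered from hydrophilic to hydrophobic,
#' binned on the normalized Kyte-Doolittle scale) or 7
#' conformational-similarity groups (`"conform"`, labels `C_1`..`C_7`,
#' after Pal & Chakrabarti). Any grouping can be supplied instead as a
#' two-column tab-separated mapping file (`amino_acid`, `group_label`,
#' `#` comments allowed) that covers all 20 residues.
#'
#' @param name_or_path one of `"no_reduction"`, `"hydro"`, `"conform"`, or a
#'   path to a mapping TSV.
#' @return an object of class `aa_alphabet`: a list with `name`,
#'   `symbols` (ordered, distinct group labels) and `mapping` (named
#'   character vector, one entry per amino acid).
#' @examples
#' load_alphabet("hydro")$symbols
#' @export
load_alphabet <- function(name_or_path) {
  stopifnot(is.character(name_or_path), length(name_or_path) == 1L)
  if (name_or_path == "no_reduction") {
    mapping <- stats::setNames(AA20, AA20)
    return(new_alphabet("no_reduction", mapping))
  }
  if (name_or_path %in% c("hydro", "conform")) {
    path <- system.file("extdata", "alphabets",
                        paste0(name_or_path, ".tsv"),
                        package = "ampfeatr", mustWork = TRUE)
    return(read_alphabet_tsv(path, name = name_or_path))
  }
  if (file.exists(name_or_path)) {
    return(read_alphabet_tsv(name_or_path,
                             name = tools::file_path_sans_ext(basename(name_or_path))))
  }
  stop("unknown alphabet '", name_or_path,
       "': not a built-in name (no_reduction, hydro, conform) ",
       "and no such mapping file", call. = FALSE)
}

read_alphabet_tsv <- function(path, name) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("amino_acid", "group_label"),
                           colClasses = "character", strip.white = TRUE)
  tab$amino_acid <- toupper(tab$amino_acid)
  if (anyDuplicated(tab$amino_acid))
    stop("duplicate amino-acid rows in mapping file: ",
         paste(unique(tab$amino_acid[duplicated(tab$amino_acid)]), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(AA20, tab$amino_acid)
  if (length(missing))
    stop("mapping file is not total over the 20 amino acids; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(tab$amino_acid, AA20)
  if (length(extra))
    stop("mapping file contains non-standard amino acids: ",
         paste(extra, collapse = ", "), call. = FALSE)
  mapping <- stats::setNames(tab$group_label, tab$amino_acid)[AA20]
  new_alphabet(name, mapping)
}

new_alphabet <- function(name, mapping) {
  # symbol order: first appearance in the table for reduced alphabets,
  # sorted naturally for labels of the form X_i so H_1 < H_2 < ... holds
  symbols <- unique(unname(mapping))
  if (all(grepl("^[A-Za-z]+_[0-9]+$", symbols))) {
    idx <- as.integer(sub("^.*_", "", symbols))
    symbols <- symbols[order(idx)]
  }
  structure(list(name = name, symbols = symbols, mapping = mapping),
            class = "aa_alphabet")
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("<aa_alphabet>", x$name, "-", length(x$symbols), "symbols\n")
  for (s in x$symbols)
    cat(" ", s, ":", paste(names(x$mapping)[x$mapping == s], collapse = ""), "\n")
  invisible(x)
}

#' Re-encode an amino-acid sequence under an alphabet
#'
#' Applies the alphabet mapping position-wise; length is preserved. Lowercase
#' letters are uppercased before lookup. Any character outside the 20
#' standard amino acids (including the padding letter `X`) is an error that
#' names the offending position.
#'
#' @param sequence a single amino-acid string.
#' @param alphabet an `aa_alphabet` or a name accepted by [load_alphabet()].
#' @param source_id identifier carried along with the encoded sequence.
#' @return an object of class `rep_seq`: list with `alphabet`, `tokens`
#'   (character vector of symbols) and `source_id`.
#' @examples
#' reduce_sequence("ACDEF", load_alphabet("hydro"))$tokens
#' @export
reduce_sequence <- function(sequence, alphabet, source_id = NA_character_) {
  if (is.character(alphabet)) alphabet <- load_alphabet(alphabet)
  stopifnot(inherits(alphabet, "aa_alphabet"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single nonempty string", call. = FALSE)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA20))
  if (length(bad))
    stop("non-standard residue '", chars[bad[1]], "' at position ", bad[1],
         if (!is.na(source_id)) paste0(" in sequence '", source_id, "'"),
         call. = FALSE)
  structure(list(alphabet = alphabet,
                 tokens = unname(alphabet$mapping[chars]),
                 source_id = source_id),
            class = "rep_seq")
}

#' @export
print.rep_seq <- function(x, ...) {
  cat("<rep_seq>", if (!is.na(x$source_id)) x$source_id, "(",
      x$alphabet$name, "):", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}
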