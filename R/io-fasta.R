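#' Read sequences from a FASTA file
#'
#' Record ids are stripped at the first whitespace and sequences are
#' uppercased. Duplicate ids and characters outside the declared alphabet
#' are errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` (20 amino acids plus `X`, `*`, `-`) or
#'   `"nucleotide"` (IUPAC codes plus `-`).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  assert_that(file.exists(path), paste0("FASTA file not found: ", path))
  set <- if (alphabet == "protein") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  pattern <- if (alphabet == "protein") {
    "^[ACDEFGHIKLMNPQRSTVWYX*-]*$"
  } else {
    "^[ACGTUNRYSWKMBDHV-]*$"
  }
  bad <- ids[!grepl(pattern, seqs)]
  if (length(bad)) {
    abort(paste0("illegal ", alphabet, " character(s) in sequence(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns, so reading and rewriting a file
#' produced by this writer is byte-identical.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  assert_that(!is.null(names(seqs)) && all(nzchar(names(seqs))),
              "all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
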