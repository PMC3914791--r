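#' Domain labels recognised in domain-hit tables
#' @export
DOMAIN_LABELS <- c("NB-ARC", "TIR", "LRR", "CC", "BED", "kinase")

#' Read a domain-hit table
#'
#' The table is a minimal 5-column TSV with header
#' `gene_id, domain, aa_start, aa_end, score`, one row per domain interval
#' on a protein (residue coordinates, 0-based half-open). This dialect
#' decouples the pipeline from any particular profile-HMM search tool: a
#' HMMER `--domtblout` file can be converted by extracting the target name,
#' the query (domain) name, the envelope coordinates minus one on the
#' start, and the domain bit score.
#'
#' Rows are grouped by gene and sorted by `aa_start`, so the result is
#' invariant to the input row order.
#'
#' @param path path to the TSV file.
#' @return Tibble with the five columns above.
#' @export
read_domain_hits <- function(path) {
  hits <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    domain = readr::col_character(),
    aa_start = readr::col_integer(),
    aa_end = readr::col_integer(),
    score = readr::col_double()
  ), progress = FALSE)
  validate_domain_hits(hits)
}

validate_domain_hits <- function(hits) {
  unknown <- setdiff(unique(hits$domain), DOMAIN_LABELS)
  if (length(unknown)) {
    abort(paste0("unknown domain label(s): ", paste(unknown, collapse = ", ")))
  }
  bad <- hits$aa_start >= hits$aa_end
  if (any(bad)) {
    abort(paste0("domain hit with aa_start >= aa_end for gene(s): ",
                 paste(unique(hits$gene_id[bad]), collapse = ", ")))
  }
  hits |> arrange(.data$gene_id, .data$aa_start, .data$aa_end, .data$domain)
}

#' Write a domain-hit table
#' @param hits tibble as returned by [read_domain_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}
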