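#' Global protein similarity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gap penalties) of
#' two protein sequences; similarity is the fraction of identical columns
#' over all alignment columns after terminal gap columns are trimmed.
#'
#' @param a,b protein sequences (strings).
#' @return Similarity in \[0, 1\].
#' @export
protein_similarity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- sa == "-" | sb == "-"
  first <- which(!gap)[1]
  last <- tail(which(!gap), 1)
  keep <- seq(first, last)
  sum(sa[keep] == sb[keep]) / length(keep)
}

#' Collapse putative alleles among RGA records
#'
#' On heterozygous assemblies the same gene can be predicted twice. Two
#' records on the same scaffold whose genomic intervals intersect and whose
#' global protein similarity exceeds `similarity_threshold` are treated as
#' alleles of one gene; connected components are formed transitively, the
#' longest protein in each component (ties: lexicographically smallest id)
#' becomes the representative, and every other member is marked
#' `is_allele`. Alleles are excluded from clustering, summaries, phylogeny
#' and Ks downstream.
#'
#' @param records RGA record tibble (see [promote_to_rga()]).
#' @param proteins named character vector of protein sequences.
#' @param similarity_threshold pairs join when similarity is strictly
#'   greater than this fraction (default 0.90).
#' @return `records` with `is_allele` and `representative_id` set; row
#'   order is by scaffold and start, independent of input order.
#' @export
collapse_alleles <- function(records, proteins, similarity_threshold = 0.90) {
  records <- records |> arrange(.data$scaffold, .data$start, .data$gene_id)
  n <- nrow(records)
  if (n == 0) return(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  by_scaffold <- split(seq_len(n), records$scaffold)
  for (idx in by_scaffold) {
    if (length(idx) < 2) next
    for (u in seq_along(idx)[-length(idx)]) {
      for (v in seq(u + 1, length(idx))) {
        i <- idx[u]; j <- idx[v]
        if (records$start[i] < records$end[j] && records$end[i] > records$start[j]) {
          pi_ <- proteins[[records$gene_id[i]]]
          pj_ <- proteins[[records$gene_id[j]]]
          if (is.null(pi_) || is.null(pj_)) {
            missing <- c(records$gene_id[i], records$gene_id[j])[
              c(is.null(pi_), is.null(pj_))]
            abort(paste0("missing protein sequence for compared gene(s): ",
                         paste(missing, collapse = ", ")))
          }
          if (protein_similarity(pi_, pj_) > similarity_threshold) union_(i, j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  records$is_allele <- FALSE
  records$representative_id <- records$gene_id
  for (cid in unique(comp[duplicated(comp)])) {
    members <- which(comp == cid)
    lens <- vapply(records$gene_id[members],
                   function(id) nchar(proteins[[id]]), numeric(1))
    ord <- order(-lens, records$gene_id[members])
    rep_idx <- members[ord[1]]
    others <- setdiff(members, rep_idx)
    records$is_allele[others] <- TRUE
    records$representative_id[others] <- records$gene_id[rep_idx]
  }
  records
}
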