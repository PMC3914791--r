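#' The nine RGA architecture classes
#'
#' Classes are named by the left-to-right order of the TIR (T), coiled-coil
#' (C), NBS (N, the NB-ARC domain) and LRR (L) tokens along the protein.
#' The TIR-NBS superclass contains TNL, NLT, TCNL, TCN and TN; the
#' non-TIR-NBS-LRR superclass contains CNL and NL; CN and N form the
#' residual "other" superclass.
#'
#' @return Tibble with columns `class` and `superclass`.
#' @export
rga_classes <- function() {
  tibble(
    class = c("TNL", "NLT", "TCNL", "TCN", "TN", "CNL", "NL", "CN", "N"),
    superclass = c(rep("TIR-NBS", 5), rep("non-TIR-NBS-LRR", 2), rep("other", 2))
  )
}

class_superclass <- function(class) {
  map <- setNames(rga_classes()$superclass, rga_classes()$class)
  unname(map[class])
}

#' Classify one protein's domain architecture
#'
#' Reads the class label off the left-to-right order of the first
#' occurrences of the TIR, CC, NBS (NB-ARC) and LRR tokens. A coiled-coil
#' detected by propensity scoring (rather than an explicit CC hit)
#' contributes a C token immediately before the N token, reflecting its
#' N-terminal role. If the resulting token string is not one of the nine
#' class names, the label is the longest class name that is a subsequence
#' of the token string (ties broken towards the N-terminus, then
#' alphabetically); N is always a fallback.
#'
#' @param hits tibble of domain hits for a single gene (columns `domain`,
#'   `aa_start`, `aa_end`), in any order.
#' @param has_cc logical; TRUE when coiled-coil scoring fired for this
#'   protein.
#' @return A list with `class` (NA when the gene has no NB-ARC hit and is
#'   therefore not an RGA), `superclass`, and `flags` (character vector;
#'   `multi_nbs` when more than one NB-ARC hit is present — classification
#'   then uses the first).
#' @export
classify_architecture <- function(hits, has_cc = FALSE) {
  flags <- character()
  nbs <- hits[hits$domain == "NB-ARC", , drop = FALSE]
  if (nrow(nbs) == 0) {
    return(list(class = NA_character_, superclass = NA_character_, flags = flags))
  }
  if (nrow(nbs) > 1) flags <- c(flags, "multi_nbs")
  if ("BED" %in% hits$domain) flags <- c(flags, "bed")
  if ("kinase" %in% hits$domain) flags <- c(flags, "kinase")

  token_of <- c("TIR" = "T", "CC" = "C", "NB-ARC" = "N", "LRR" = "L")
  first <- hits |>
    filter(.data$domain %in% names(token_of)) |>
    group_by(.data$domain) |>
    summarise(at = min(.data$aa_start), .groups = "drop") |>
    arrange(.data$at)
  tokens <- unname(token_of[first$domain])
  if (has_cc && !("C" %in% tokens)) {
    npos <- match("N", tokens)
    tokens <- append(tokens, "C", after = npos - 1L)
  }
  order_string <- paste(tokens, collapse = "")
  list(class = match_class_grammar(order_string),
       superclass = class_superclass(match_class_grammar(order_string)),
       flags = flags)
}

match_class_grammar <- function(order_string) {
  labels <- rga_classes()$class
  if (order_string %in% labels) return(order_string)
  is_subseq <- function(lab) {
    pat <- paste0(strsplit(lab, "")[[1]], collapse = ".*")
    grepl(pat, order_string)
  }
  ok <- labels[vapply(labels, is_subseq, logical(1))]
  ok <- ok[order(-nchar(ok), ok)]
  ok[1]
}

#' Promote annotated genes with an NB-ARC domain to RGA records
#'
#' Every gene with at least one NB-ARC hit becomes an RGA record. The CC
#' token is contributed either by an explicit CC domain hit or by the
#' coiled-coil scorer at `cfg$threshold`; kinase and BED hits are recorded
#' as flags only and never change the class.
#'
#' @param annotation an `rga_annotation` (see [read_gff3()]).
#' @param hits domain-hit tibble (see [read_domain_hits()]); every
#'   `gene_id` must exist in the annotation.
#' @param proteins named character vector of protein sequences.
#' @param cfg a [coil_config()].
#' @return Tibble of RGA records: the gene columns plus `class`,
#'   `superclass`, `coil_prob`, `flags`, `is_allele`, `representative_id`,
#'   `cluster_id`, `clade_id`.
#' @export
promote_to_rga <- function(annotation, hits, proteins, cfg = coil_config()) {
  hits <- validate_domain_hits(hits)
  genes <- annotation$genes
  unknown <- setdiff(unique(hits$gene_id), genes$gene_id)
  if (length(unknown)) {
    abort(paste0("domain hits reference unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  rga_ids <- unique(hits$gene_id[hits$domain == "NB-ARC"])
  rows <- lapply(rga_ids, function(id) {
    gh <- hits[hits$gene_id == id, , drop = FALSE]
    prot <- proteins[[id]] %||% ""
    prob <- coiled_coil_max_prob(prot, cfg)
    cls <- classify_architecture(gh, has_cc = (prob >= cfg$threshold))
    flags <- cls$flags
    if (identical(attr(prob, "flag"), "short_sequence")) {
      flags <- c(flags, "short_sequence")
    }
    tibble(gene_id = id, class = cls$class, superclass = cls$superclass,
           coil_prob = as.numeric(prob), flags = flag_string(flags))
  })
  genes |>
    dplyr::inner_join(bind_rows(rows), by = "gene_id") |>
    mutate(is_allele = FALSE, representative_id = .data$gene_id,
           cluster_id = NA_character_, clade_id = NA_character_) |>
    arrange(.data$scaffold, .data$start)
}
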