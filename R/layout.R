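#' Expand a per-chromosome summary table into a concrete gene layout
#'
#' Builds a synthetic genome layout (RGA records plus background ORFs)
#' that realizes a printed per-chromosome organization table exactly: for
#' each chromosome the requested number of RGAs, singletons and clusters,
#' with cluster sizes chosen as equal as possible so they sum to the
#' clustered count. Cluster members are placed 1 kb apart with no
#' intervening ORFs; singletons and clusters are separated by 300 kb so a
#' cluster caller at default parameters recovers the planted organization
#' verbatim. Rows whose chromosome is `unanchored` contribute RGAs on
#' unplaced scaffolds.
#'
#' This is a fixture builder: the layout is synthetic and only its summary
#' statistics are meaningful.
#'
#' @param counts tibble with columns `chromosome`, `n_rgas`,
#'   `n_singletons`, `n_clusters` (e.g. read from
#'   `system.file("extdata", "apple_chromosome_counts.tsv", package =
#'   "rgatools")`).
#' @param gene_length gene interval length in bp (default 2000).
#' @return List with `records` (RGA record tibble), `annotation`
#'   (`rga_annotation`).
#' @export
layout_from_counts <- function(counts, gene_length = 2000) {
  genes <- list()
  counter <- 0L
  add_gene <- function(scaffold, chromosome, start) {
    counter <<- counter + 1L
    id <- sprintf("rga%05d", counter)
    genes[[id]] <<- tibble(
      gene_id = id, scaffold = scaffold, chromosome = chromosome,
      start = start, end = start + gene_length, strand = "+", n_exons = 4L)
    id
  }
  for (r in seq_len(nrow(counts))) {
    row <- counts[r, ]
    if (identical(row$chromosome, "unanchored")) {
      for (k in seq_len(row$n_rgas)) {
        add_gene(sprintf("S%03d", k), NA_character_, 1000)
      }
      next
    }
    n_clustered <- row$n_rgas - row$n_singletons
    sizes <- integer(0)
    if (row$n_clusters > 0) {
      base <- n_clustered %/% row$n_clusters
      extra <- n_clustered %% row$n_clusters
      sizes <- rep(base, row$n_clusters) + c(rep(1L, extra),
                                             rep(0L, row$n_clusters - extra))
      assert_that(all(sizes >= 2),
                  paste0("chromosome ", row$chromosome,
                         ": clustered count too small for cluster count"))
    }
    cursor <- 50000
    for (sz in sizes) {
      for (m in seq_len(sz)) {
        add_gene(row$chromosome, row$chromosome, cursor)
        cursor <- cursor + gene_length + 1000
      }
      cursor <- cursor + 300000
    }
    for (s in seq_len(row$n_singletons)) {
      add_gene(row$chromosome, row$chromosome, cursor)
      cursor <- cursor + gene_length + 300000
    }
  }
  genes_tbl <- bind_rows(genes) |> arrange(.data$scaffold, .data$start)
  records <- genes_tbl |>
    mutate(class = "NL", superclass = "non-TIR-NBS-LRR", coil_prob = 0,
           flags = "", is_allele = FALSE, representative_id = .data$gene_id,
           cluster_id = NA_character_, clade_id = NA_character_)
  list(records = records, annotation = new_annotation(genes_tbl))
}
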