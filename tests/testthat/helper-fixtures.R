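# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from outside the package.

.fixture_env <- new.env()

# A compact synthetic genome shared across test files (built once per run):
# a 2- and a 6-member cluster, one WGD doublet, singletons, two allele
# pairs, one chromosome biased to non-TIR classes.
small_synth_config <- function(seed = 101) {
  synth_config(
    seed = seed, n_chromosomes = 4, chromosome_length = 6e6,
    n_background_genes = 40,
    cluster_spec = tibble::tibble(
      chromosome = c("Chr01", "Chr02"), n_members = c(2L, 6L),
      spacing = c(20000, 20000), intervening = c(5L, 3L)),
    n_singleton_rgas = 8,
    allele_spec = list(n_pairs = 2, similarity = 0.96),
    wgd_spec = tibble::tibble(chr_a = "Chr03", chr_b = "Chr04",
                              n_pairs = 12L, target_ks = 0.15),
    class_bias = list(Chr03 = c("TIR-NBS" = 0.01,
                                "non-TIR-NBS-LRR" = 0.99, "other" = 0)))
}

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- generate_genome(small_synth_config())
  }
  .fixture_env$sim
}

shared_records <- function() {
  if (is.null(.fixture_env$records)) {
    sim <- shared_sim()
    recs <- promote_to_rga(sim$annotation, sim$hits, sim$proteins,
                           coil_config())
    .fixture_env$records <- collapse_alleles(recs, sim$proteins)
  }
  .fixture_env$records
}

# Minimal record/annotation builder for layout-level tests: genes given as
# a tibble with gene_id, chromosome, start, end, is_rga.
toy_layout <- function(genes) {
  genes <- genes |>
    dplyr::mutate(
      scaffold = .data$chromosome,
      strand = "+", n_exons = 1L) |>
    dplyr::arrange(.data$scaffold, .data$start)
  annotation <- rgatools:::new_annotation(
    genes |> dplyr::select("gene_id", "scaffold", "chromosome", "start",
                           "end", "strand", "n_exons"))
  records <- genes |>
    dplyr::filter(.data$is_rga) |>
    dplyr::transmute(
      gene_id = .data$gene_id, scaffold = .data$scaffold,
      chromosome = .data$chromosome, start = .data$start, end = .data$end,
      strand = .data$strand, n_exons = .data$n_exons,
      class = "NL", superclass = "non-TIR-NBS-LRR", coil_prob = 0,
      flags = "", is_allele = FALSE, representative_id = .data$gene_id,
      cluster_id = NA_character_, clade_id = NA_character_)
  list(records = records, annotation = annotation)
}

# Random single-chromosome gene layout for cluster-oracle tests.
random_layout <- function(n_genes, chrom = "ChrT") {
  starts <- sort(sample.int(2e6, n_genes))
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chromosome = chrom,
    start = starts,
    end = starts + sample(500:3000, n_genes, replace = TRUE),
    is_rga = sample(c(TRUE, FALSE), n_genes, replace = TRUE, prob = c(.4, .6)))
}

# Brute-force cluster oracle: tests every contiguous run of RGAs on a
# chromosome against both chaining conditions and keeps maximal runs.
oracle_clusters <- function(layout, max_gap, max_intervening) {
  rga <- layout[layout$is_rga, ]
  rga <- rga[order(rga$start), ]
  orf <- layout[!layout$is_rga, ]
  k <- nrow(rga)
  if (k == 0) return(list())
  run_ok <- function(i, j) {
    for (u in seq(i, j - 1)) {
      gap <- rga$start[u + 1] - rga$end[u]
      nb <- sum(orf$start >= rga$end[u] & orf$end <= rga$start[u + 1])
      if (gap > max_gap || nb > max_intervening) return(FALSE)
    }
    TRUE
  }
  out <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && run_ok(j, j + 1)) j <- j + 1
    if (j > i) out[[length(out) + 1]] <- rga$gene_id[i:j]
    i <- j + 1
  }
  out
}

# Brute-force single-group clade oracle: scans every internal node.
oracle_single_group_clades <- function(tree, map, min_size) {
  n_tip <- length(tree$tip.label)
  desc <- rgatools:::descendant_leaf_sets(tree)
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  hits <- list()
  for (v in seq_len(tree$Nnode)) {
    leaves <- desc[[v]]
    g <- unique(unname(map[leaves]))
    if (length(g) != 1 || length(leaves) < min_size) next
    p <- parent_of[v + n_tip]
    if (p != 0) {
      pg <- unique(unname(map[desc[[p - n_tip]]]))
      if (length(pg) == 1) next
    }
    hits[[length(hits) + 1]] <- list(group = g, leaves = sort(leaves))
  }
  hits[order(vapply(hits, function(h) paste(h$leaves, collapse = ","),
                    character(1)))]
}

# Forward simulation of synonymous-only codon evolution, independent of
# the NG86 implementation: the derived sequence receives exactly
# `round(ks_true * S)` random synonymous substitution events (multiple
# hits at one site allowed), with S counted here from the genetic code
# directly.
simulate_ng86_pair <- function(n_codons, ks_true) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  bases <- c("T", "C", "A", "G")
  syn_sites_of <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- b
        if (gc[[alt]] != "*" && gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  anc <- sample(sense, n_codons, replace = TRUE)
  S <- sum(vapply(anc, syn_sites_of, numeric(1)))
  der <- anc
  n_events <- round(ks_true * S)
  applied <- 0
  while (applied < n_events) {
    i <- sample.int(n_codons, 1)
    pos <- sample.int(3, 1)
    b <- sample(setdiff(bases, substr(der[i], pos, pos)), 1)
    alt <- der[i]
    substr(alt, pos, pos) <- b
    if (gc[[alt]] != "*" && gc[[alt]] == gc[[der[i]]]) {
      der[i] <- alt
      applied <- applied + 1
    }
  }
  list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""))
}

# random unrooted tree with branch lengths; distances from it are additive
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   tip.label = sprintf("L%02d", seq_len(n_leaves)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}
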