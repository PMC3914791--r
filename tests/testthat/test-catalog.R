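aa_string <- function(n, seed) {
  set.seed(seed)
  paste(sample(rownames(coils_propensity_table()), n, replace = TRUE),
        collapse = "")
}

substitute_at <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (i in positions) ch[i] <- setdiff(c("A", "G", "S"), ch[i])[1]
  paste(ch, collapse = "")
}

allele_records <- function(n, scaffold = "S001") {
  tibble::tibble(
    gene_id = sprintf("a%d", seq_len(n)), scaffold = scaffold,
    chromosome = NA_character_,
    start = seq(0, by = 500, length.out = n), end = 2000 + seq_len(n) * 100,
    strand = "+", n_exons = 1L, class = "NL",
    superclass = "non-TIR-NBS-LRR", coil_prob = 0, flags = "",
    is_allele = FALSE, representative_id = sprintf("a%d", seq_len(n)),
    cluster_id = NA_character_, clade_id = NA_character_)
}

test_that("identical overlapping duplicates collapse to one representative", {
  recs <- allele_records(2)
  prot <- aa_string(150, 21)
  out <- collapse_alleles(recs, c(a1 = prot, a2 = prot))
  expect_equal(sum(out$is_allele), 1)
  expect_equal(unique(out$representative_id[!out$is_allele]),
               out$representative_id[out$is_allele])
})

test_that("overlapping pairs below the similarity threshold are kept", {
  recs <- allele_records(2)
  prot <- aa_string(200, 22)
  diverged <- substitute_at(prot, 1:30)  # 85% identity
  out <- collapse_alleles(recs, c(a1 = prot, a2 = diverged))
  expect_equal(sum(out$is_allele), 0)
})

test_that("allele components form transitively with the longest protein as representative", {
  recs <- allele_records(3)
  base <- aa_string(200, 23)
  pa <- paste0(base, "GG")                    # longest -> representative
  pb <- substitute_at(base, 1:10)             # ~95% to a
  pc <- substitute_at(base, c(1:10, 101:110)) # ~95% to b, 90% to a (below)
  expect_lte(protein_similarity(pa, pc), 0.905)
  out <- collapse_alleles(recs, c(a1 = pa, a2 = pb, a3 = pc))
  expect_equal(sum(out$is_allele), 2)
  expect_equal(unique(out$representative_id[out$is_allele]), "a1")
  # invariant to input ordering
  out2 <- collapse_alleles(recs[c(3, 1, 2), ], c(a1 = pa, a2 = pb, a3 = pc))
  expect_equal(out2 |> dplyr::arrange(gene_id),
               out |> dplyr::arrange(gene_id))
})

test_that("planted alleles in the synthetic genome are recovered", {
  sim <- shared_sim()
  recs <- shared_records()
  truth <- sim$truth$genes
  expect_setequal(recs$gene_id[recs$is_allele],
                  truth$gene_id[truth$kind == "allele"])
})

test_that("basic chaining: gap and intervening-ORF conditions both bind", {
  two_rga <- function(n_between, gap = 100000) {
    genes <- tibble::tibble(
      gene_id = c("r1", sprintf("o%d", seq_len(n_between)), "r2"),
      chromosome = "ChrT",
      start = c(0, seq(2000, by = 1000, length.out = n_between), gap + 2000),
      end = c(1000, seq(2500, by = 1000, length.out = n_between), gap + 3000),
      is_rga = c(TRUE, rep(FALSE, n_between), TRUE))
    toy_layout(genes)
  }
  l1 <- two_rga(5)
  cl1 <- call_clusters(l1$records, l1$annotation, cluster_config())
  expect_equal(nrow(cl1$clusters), 1)
  expect_equal(cl1$clusters$n_members, 2)

  l2 <- two_rga(22)
  cl2 <- call_clusters(l2$records, l2$annotation, cluster_config())
  expect_equal(nrow(cl2$clusters), 0)
  expect_equal(nrow(cl2$singletons), 2)

  l3 <- two_rga(5, gap = 260000)
  cl3 <- call_clusters(l3$records, l3$annotation, cluster_config())
  expect_equal(nrow(cl3$clusters), 0)
})

test_that("cluster caller equals the brute-force oracle on random layouts", {
  set.seed(31)
  for (k in 1:40) {
    layout <- random_layout(sample(5:30, 1))
    toy <- toy_layout(layout)
    for (mg in c(50000, 250000)) {
      for (mi in c(0L, 3L, 21L)) {
        cl <- call_clusters(toy$records, toy$annotation,
                            cluster_config(max_gap = mg, max_intervening = mi))
        got <- lapply(cl$clusters$members, identity)
        want <- oracle_clusters(layout, mg, mi)
        expect_equal(got[order(vapply(got, `[`, character(1), 1))],
                     want[order(vapply(want, `[`, character(1), 1))])
      }
    }
  }
})

test_that("clustered count is monotone in max_gap and max_intervening", {
  set.seed(32)
  for (k in 1:10) {
    layout <- random_layout(25)
    toy <- toy_layout(layout)
    clustered <- function(mg, mi) {
      cl <- call_clusters(toy$records, toy$annotation,
                          cluster_config(mg, mi))
      sum(cl$clusters$n_members)
    }
    expect_true(all(diff(vapply(c(1e4, 1e5, 1e6), clustered,
                                numeric(1), mi = 5L)) >= 0))
    expect_true(all(diff(vapply(c(0L, 2L, 10L, 50L), clustered,
                                numeric(1), mg = 2e5)) >= 0))
  }
})

test_that("anchored records partition into clusters and singletons", {
  sim <- shared_sim()
  recs <- shared_records()
  cl <- call_clusters(recs, sim$annotation, cluster_config())
  anchored <- recs |> dplyr::filter(!is_allele, !is.na(chromosome))
  in_clusters <- unlist(cl$clusters$members)
  expect_equal(length(in_clusters) + nrow(cl$singletons), nrow(anchored))
  expect_equal(anyDuplicated(in_clusters), 0)
  expect_setequal(c(in_clusters, cl$singletons$gene_id), anchored$gene_id)
})

test_that("empty catalogs summarise to zeros without division errors", {
  empty <- allele_records(0)
  cl <- structure(list(clusters = tibble::tibble(
    cluster_id = character(), chromosome = character(), n_members = integer(),
    span_start = numeric(), span_end = numeric(), members = list()),
    singletons = tibble::tibble(gene_id = character(),
                                chromosome = character())),
    class = "rga_clusters")
  s <- summarize_catalog(empty, cl, n_predicted_genes = 1000, genome_mb = 10)
  expect_equal(s$totals$n_rgas, 0)
  expect_equal(s$totals$pct_clustered, 0)
  expect_error(summarize_catalog(empty, cl, 0, 10), "n_predicted_genes")
})

test_that("crosstab reproduces degenerate and planted compositions", {
  recs <- allele_records(4) |>
    dplyr::mutate(chromosome = "Chr1", class = c("TNL", "TNL", "NL", "NL"),
                  superclass = c("TIR-NBS", "TIR-NBS", "non-TIR-NBS-LRR",
                                 "non-TIR-NBS-LRR"))
  xt <- class_chromosome_crosstab(recs)
  expect_true(all(xt$by_class$row_pct == 100))  # single chromosome
  recs2 <- recs |> dplyr::mutate(chromosome = c("Chr1", "Chr2", "Chr1", "Chr2"))
  xt2 <- class_chromosome_crosstab(recs2)
  expect_true(all(xt2$by_class$row_pct == 50))
  expect_true(all(xt2$by_class$col_pct == 50))
})

test_that("the planted chromosome class bias is visible in the crosstab", {
  recs <- shared_records()
  xt <- class_chromosome_crosstab(recs)$by_superclass
  chr3 <- xt |> dplyr::filter(chromosome == "Chr03")
  nontir <- chr3$col_pct[chr3$superclass == "non-TIR-NBS-LRR"]
  expect_gte(nontir, 90)
})

test_that("exon-count comparison computes means and a rank-test p-value", {
  recs <- allele_records(4) |>
    dplyr::mutate(class = c("CNL", "CNL", "TNL", "TNL"),
                  n_exons = c(2L, 4L, 6L, 8L))
  res <- compare_exon_counts(recs, groups = c("CNL", "TNL"))
  expect_equal(res$means$mean_exons, c(3.00, 7.00))

  same <- allele_records(20) |>
    dplyr::mutate(class = rep(c("CNL", "TNL"), each = 10),
                  n_exons = rep(c(1L, 2L, 3L, 4L, 5L), 4))
  expect_gt(compare_exon_counts(same)$p_value, 0.9)

  set.seed(33)
  shifted <- allele_records(400) |>
    dplyr::mutate(class = rep(c("CNL", "TNL"), each = 200),
                  n_exons = c(rpois(200, 3) + 1L, rpois(200, 3) + 4L))
  expect_lt(compare_exon_counts(shifted)$p_value, 0.001)
})
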