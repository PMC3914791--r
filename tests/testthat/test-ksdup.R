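test_that("codon alignment threads CDS onto protein alignments", {
  cds <- strrep("ATGGTC", 5)  # MVMVMVMVMV (10 codons)
  prot <- "MVMVMVMVMV"
  ca <- codon_align(prot, prot, cds, cds)
  expect_equal(nchar(ca$a), 30)
  expect_equal(ca$a, cds)

  # one-residue gap becomes one gap triple at the matching position
  ca2 <- codon_align("MV-MV", "MVMMV", "ATGGTCATGGTC", "ATGGTCATGATGGTC")
  expect_equal(ca2$a, "ATGGTC---ATGGTC")
  expect_equal(ca2$b, "ATGGTCATGATGGTC")

  # terminal stop codons are tolerated and dropped
  ca3 <- codon_align(prot, prot, paste0(cds, "TAA"), cds)
  expect_equal(ca3$a, cds)

  expect_error(codon_align("MM", "MM", "ATGTAAATG", "ATGATG"), "stop")
  expect_error(codon_align("MK", "MK", "ATGATG", "ATGATG"), "mismatch")
})

test_that("random back-threaded alignments reproduce both CDS exactly", {
  set.seed(51)
  by_aa <- split(names(Biostrings::GENETIC_CODE),
                 unname(Biostrings::GENETIC_CODE))
  rev_tr <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(r)
      sample(by_aa[[r]], 1), character(1)), collapse = "")
  }
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  for (k in 1:20) {
    pa <- paste(sample(aas, 40, replace = TRUE), collapse = "")
    pb <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    cds_a <- rev_tr(pa)
    cds_b <- rev_tr(pb)
    aln <- align_protein_pair(pa, pb)
    ca <- codon_align(aln$a, aln$b, cds_a, cds_b)
    expect_equal(nchar(ca$a) %% 3, 0)
    expect_equal(nchar(ca$a), nchar(ca$b))
    # back-translation: removing gaps reproduces both CDS exactly
    expect_equal(gsub("-", "", ca$a), cds_a)
    expect_equal(gsub("-", "", ca$b), cds_b)
  }
})

test_that("NG86 matches the hand-computed worked example", {
  a <- strrep("TTT", 10)
  b <- paste0(strrep("TTT", 9), "TTC")
  est <- ng86(a, b)
  expect_equal(est$S, 10 / 3, tolerance = 1e-12)
  expect_equal(est$N, 30 - 10 / 3, tolerance = 1e-12)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$ps, 0.3, tolerance = 1e-12)
  expect_equal(round(est$ks, 4), 0.3831)  # -0.75 ln(0.6)

  ident <- ng86(a, a)
  expect_equal(ident$Sd, 0)
  expect_equal(ident$ks, 0)
})

test_that("NG86 site counts satisfy S + N = 3 x codons and flag saturation", {
  set.seed(52)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (k in 1:10) {
    a <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    b <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    est <- ng86(a, b)
    expect_equal(est$S + est$N, 3 * est$n_codons, tolerance = 1e-9)
  }
  # every third position differs synonymously: ps = Sd/S well above 0.75
  sat <- ng86(strrep("TTT", 20), strrep("TTC", 20))
  expect_true(is.na(sat$ks))
  expect_match(sat$flags, "saturated")
  # gap codons are skipped pairwise
  gapped <- ng86(paste0("---", strrep("TTT", 5)), strrep("TTT", 6))
  expect_equal(gapped$n_codons, 5L)
})

test_that("the Jukes-Cantor correction is monotone in ps below saturation", {
  # pairs constructed with increasing synonymous difference fractions
  ks_at <- function(n_diff) {
    a <- strrep("GGT", 30)
    b <- paste0(strrep("GGC", n_diff), strrep("GGT", 30 - n_diff))
    ng86(a, b)$ks
  }
  vals <- vapply(c(1, 3, 6, 10, 15), ks_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("NG86 recovers the true divergence of forward-simulated pairs", {
  set.seed(53)
  for (ks_true in c(0.05, 0.1, 0.2)) {
    ests <- vapply(1:30, function(k) {
      pair <- simulate_ng86_pair(300, ks_true)
      ng86(pair$a, pair$b)$ks
    }, numeric(1))
    expect_equal(mean(ests), ks_true, tolerance = 0.1)
  }
})

test_that("pair enumeration is n(n-1)/2 over the scoped records and order-invariant", {
  recs <- tibble::tibble(
    gene_id = c("g4", "g1", "g3", "g2", "g5"),
    chromosome = c("Chr1", "Chr1", "Chr2", NA, "Chr2"),
    is_allele = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  p <- ks_pairs(recs, scope = "anchored_only")
  expect_equal(nrow(p), choose(3, 2))
  expect_true(all(p$gene_a < p$gene_b))
  expect_equal(ks_pairs(recs[c(3, 5, 1, 2, 4), ], scope = "anchored_only"), p)
  expect_equal(nrow(ks_pairs(recs, scope = "all")), choose(4, 2))
})

test_that("all-pairs Ks reports every pair and errors on missing CDS", {
  sim <- shared_sim()
  recs <- shared_records()
  sub <- recs |> dplyr::filter(!is_allele, chromosome %in% "Chr03") |>
    dplyr::slice_head(n = 6)
  est <- all_pairs_ks(sub, sim$cds, sim$proteins)
  expect_equal(nrow(est), choose(6, 2))
  expect_true(all(est$S + est$N == 3 * est$n_codons))
  cds_missing <- sim$cds[setdiff(names(sim$cds), sub$gene_id[1])]
  expect_error(all_pairs_ks(sub, cds_missing, sim$proteins),
               sub$gene_id[1])
})

test_that("chromosome links obey the pair-count threshold exactly", {
  mk_est <- function(n, chr_a, chr_b, ks = 0.1) {
    tibble::tibble(gene_a = sprintf("%s_g%d", chr_a, seq_len(n)),
                   gene_b = sprintf("%s_g%d", chr_b, seq_len(n) + 100),
                   ks = ks)
  }
  recs_for <- function(est) {
    tibble::tibble(
      gene_id = c(est$gene_a, est$gene_b),
      chromosome = sub("_g.*", "", c(est$gene_a, est$gene_b)))
  }
  e9 <- mk_est(9, "Chr1", "Chr2")
  l9 <- chromosome_links(e9, recs_for(e9), link_config())
  expect_false(any(l9$accepted))
  e10 <- mk_est(10, "Chr1", "Chr2")
  l10 <- chromosome_links(e10, recs_for(e10), link_config())
  expect_true(all(l10$accepted))
})

test_that("link acceptance is monotone in threshold and anti-monotone in min_pairs", {
  set.seed(54)
  est <- tibble::tibble(
    gene_a = sprintf("Chr1_g%d", 1:40),
    gene_b = sprintf("Chr2_g%d", 1:40),
    ks = runif(40, 0, 0.6))
  recs <- tibble::tibble(gene_id = c(est$gene_a, est$gene_b),
                         chromosome = rep(c("Chr1", "Chr2"), each = 40))
  n_acc <- function(th, mp) {
    l <- chromosome_links(est, recs, link_config(th, mp))
    sum(l$accepted)
  }
  expect_true(all(diff(vapply(c(0.1, 0.25, 0.5), n_acc,
                              numeric(1), mp = 5)) >= 0))
  expect_true(all(diff(vapply(c(1, 10, 30), function(mp)
    n_acc(0.25, mp), numeric(1))) <= 0))
})

test_that("intra-chromosome duplication shows up as accepted self-links", {
  est <- tibble::tibble(gene_a = sprintf("Chr5_g%d", 1:12),
                        gene_b = sprintf("Chr5_h%d", 1:12), ks = 0.05)
  recs <- tibble::tibble(gene_id = c(est$gene_a, est$gene_b),
                         chromosome = "Chr5")
  l <- chromosome_links(est, recs, link_config())
  expect_equal(nrow(l), 1)
  expect_equal(l$chr_a, l$chr_b)
  expect_true(l$accepted)
})
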