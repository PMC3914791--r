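mk_hits <- function(domains, starts) {
  tibble::tibble(gene_id = "g", domain = domains, aa_start = as.integer(starts),
                 aa_end = as.integer(starts + 30), score = 50)
}

test_that("architecture grammar reads classes off token order", {
  expect_equal(classify_architecture(
    mk_hits(c("TIR", "NB-ARC", "LRR"), c(0, 100, 300)))$class, "TNL")
  expect_equal(classify_architecture(mk_hits("NB-ARC", 100))$class, "N")
  expect_equal(classify_architecture(mk_hits("NB-ARC", 100), has_cc = TRUE)$class,
               "CN")
  expect_equal(classify_architecture(
    mk_hits(c("NB-ARC", "LRR", "TIR"), c(0, 100, 300)))$class, "NLT")
  expect_equal(classify_architecture(
    mk_hits(c("TIR", "NB-ARC", "LRR"), c(0, 100, 300)), has_cc = TRUE)$class,
    "TCNL")
  expect_equal(classify_architecture(
    mk_hits(c("NB-ARC", "LRR"), c(0, 100)), has_cc = TRUE)$class, "CNL")
  # no NB-ARC -> not an RGA
  expect_true(is.na(classify_architecture(mk_hits("LRR", 0))$class))
  expect_true(is.na(classify_architecture(mk_hits(character(), integer()))$class))
})

test_that("multi-NBS proteins classify on the first hit and are flagged", {
  res <- classify_architecture(
    mk_hits(c("TIR", "NB-ARC", "NB-ARC", "LRR"), c(0, 100, 200, 300)))
  expect_equal(res$class, "TNL")
  expect_true("multi_nbs" %in% res$flags)
})

test_that("kinase and BED are annotation-only flags, never class tokens", {
  res <- classify_architecture(
    mk_hits(c("NB-ARC", "kinase", "BED"), c(0, 100, 200)))
  expect_equal(res$class, "N")
  expect_setequal(intersect(res$flags, c("kinase", "bed")), c("kinase", "bed"))
})

test_that("class labels partition into the fixed superclasses", {
  cls <- rga_classes()
  expect_equal(nrow(cls), 9)
  expect_equal(cls$superclass[match(c("TNL", "NLT", "TCNL", "TCN", "TN"),
                                    cls$class)], rep("TIR-NBS", 5))
  expect_equal(cls$superclass[match(c("CNL", "NL"), cls$class)],
               rep("non-TIR-NBS-LRR", 2))
  expect_equal(cls$superclass[match(c("CN", "N"), cls$class)], rep("other", 2))
})

test_that("coiled-coil scoring separates heptads, disorder, and short input", {
  heptads <- paste0(strrep("GNDSTH", 3), strrep("LEALEGK", 5), strrep("TSDNG", 3))
  expect_gte(coiled_coil_max_prob(heptads), 0.9)
  expect_lt(coiled_coil_max_prob(strrep("P", 50)), 0.1)
  short <- coiled_coil_max_prob(strrep("L", 10))
  expect_equal(as.numeric(short), 0)
  expect_equal(attr(short, "flag"), "short_sequence")
  # frame invariance: prefixing residues must not lose the signal
  expect_gte(coiled_coil_max_prob(paste0("G", heptads)), 0.9)
  expect_gte(coiled_coil_max_prob(paste0("GSD", heptads)), 0.9)
})

test_that("raising the coil threshold never increases CC-bearing labels", {
  sim <- shared_sim()
  cc_labels <- c("CN", "CNL", "TCN", "TCNL")
  counts <- vapply(c(0.5, 0.9, 0.99), function(th) {
    recs <- promote_to_rga(sim$annotation, sim$hits, sim$proteins,
                           coil_config(threshold = th))
    sum(recs$class %in% cc_labels)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("promotion recovers every planted class exactly", {
  sim <- shared_sim()
  recs <- promote_to_rga(sim$annotation, sim$hits, sim$proteins, coil_config())
  truth <- sim$truth$genes |> dplyr::filter(.data$kind != "background")
  expect_equal(nrow(recs), nrow(truth))
  m <- dplyr::inner_join(recs |> dplyr::select("gene_id", "class"),
                         truth |> dplyr::select("gene_id", "true_class"),
                         by = "gene_id")
  expect_equal(m$class, m$true_class)
  # pure function: rerun is identical
  expect_equal(promote_to_rga(sim$annotation, sim$hits, sim$proteins,
                              coil_config()), recs)
})

test_that("hits referencing unknown genes are rejected", {
  sim <- shared_sim()
  bad <- dplyr::bind_rows(sim$hits,
                          tibble::tibble(gene_id = "ghost", domain = "NB-ARC",
                                         aa_start = 0L, aa_end = 50L, score = 1))
  expect_error(promote_to_rga(sim$annotation, bad, sim$proteins), "ghost")
})
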