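test_that("distances are zero for identical sequences and match closed forms", {
  aln <- c(a = "MKVILLE", b = "MKVILLE")
  for (m in c("dayhoff_ml", "kimura_corrected")) {
    d <- protein_distance(aln, model = m)
    expect_equal(d[1, 2], 0)
  }
  # p = 0.1 mismatch: Kimura correction -ln(1 - p - 0.2 p^2)
  aln2 <- c(a = strrep("A", 100),
            b = paste0(strrep("R", 10), strrep("A", 90)))
  d2 <- protein_distance(aln2, model = "kimura_corrected")
  expect_equal(d2[1, 2], -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-10)
})

test_that("pairwise deletion uses only mutually ungapped columns", {
  aln <- c(a = "MKV-LLE", b = "MKVILLE", c = "MKVILL-")
  d <- protein_distance(aln, model = "kimura_corrected")
  expect_equal(d[1, 2], 0)  # 6 comparable, all equal
  expect_error(protein_distance(c(a = "M--", b = "-KV"), "kimura_corrected"),
               "no comparable columns")
})

test_that("Dayhoff ML distances agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  sim <- generate_alignment(n_leaves = 6, n_columns = 400, rate = 0.4, seed = 3)
  d1 <- protein_distance(sim$alignment, model = "dayhoff_ml")
  m <- do.call(rbind, strsplit(sim$alignment, ""))
  rownames(m) <- names(sim$alignment)
  d2 <- as.matrix(phangorn::dist.ml(phangorn::phyDat(m, type = "AA"),
                                    model = "Dayhoff"))
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-3)
})

test_that("Dayhoff ML recovers the simulated divergence of PAM-50 pairs", {
  pair_tree <- structure(list(
    edge = rbind(c(3L, 1L), c(3L, 2L)), tip.label = c("x", "y"),
    edge.length = c(0.25, 0.25), Nnode = 1L), class = "phylo")
  ests <- vapply(1:20, function(k) {
    sim <- generate_alignment(n_columns = 500, seed = 100 + k, tree = pair_tree)
    protein_distance(sim$alignment, model = "dayhoff_ml")[1, 2]
  }, numeric(1))
  expect_equal(mean(ests), 0.5, tolerance = 0.2)  # 0.5 +- 0.1 expected subs/site
})

test_that("neighbor joining solves the 3-taxon case analytically", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(41)
  for (k in 1:20) {
    gen <- random_additive_matrix(8)
    tr <- neighbor_joining(gen$dm)
    expect_equal(ape::dist.topo(tr, ape::unroot(gen$tree)), 0,
                 ignore_attr = TRUE)
    back <- ape::cophenetic.phylo(tr)[rownames(gen$dm), colnames(gen$dm)]
    expect_lt(max(abs(back - gen$dm)), 1e-9)
  }
})

test_that("neighbor joining is invariant to input label order", {
  set.seed(42)
  gen <- random_additive_matrix(10)
  perm <- sample(nrow(gen$dm))
  t1 <- neighbor_joining(gen$dm)
  t2 <- neighbor_joining(gen$dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(t1)
  d2 <- ape::cophenetic.phylo(t2)[rownames(d1), colnames(d1)]
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(43)
  sim <- generate_alignment(n_leaves = 7, n_columns = 300, rate = 0.3, seed = 9)
  dm <- protein_distance(sim$alignment, model = "dayhoff_ml")
  t1 <- neighbor_joining(dm)
  t2 <- ape::nj(as.dist(dm))
  expect_equal(ape::dist.topo(t1, ape::unroot(t2)), 0, ignore_attr = TRUE)
})

test_that("an identity resample reproduces the point-estimate tree", {
  sim <- generate_alignment(n_leaves = 5, n_columns = 200, rate = 0.3, seed = 8)
  point <- neighbor_joining(protein_distance(sim$alignment, "dayhoff_ml"))
  boots <- bootstrap_trees(sim$alignment, n_reps = 1, seed = 1,
                           resample_fun = function(n) seq_len(n))
  expect_equal(ape::dist.topo(boots[[1]], point), 0, ignore_attr = TRUE)
})

test_that("bootstrap replicates are reproducible from the seed", {
  sim <- generate_alignment(n_leaves = 5, n_columns = 120, rate = 0.3, seed = 8)
  b1 <- bootstrap_trees(sim$alignment, n_reps = 10, seed = 99)
  b2 <- bootstrap_trees(sim$alignment, n_reps = 10, seed = 99)
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
})

test_that("a strongly informative pattern dominates bootstrap support", {
  # 4 taxa: 30 columns support the (A,B)|(C,D) split, none conflict
  aln <- c(A = strrep("A", 30), B = strrep("A", 30),
           C = strrep("W", 30), D = strrep("W", 30))
  aln <- paste0(aln, strrep("G", 20))
  names(aln) <- c("A", "B", "C", "D")
  boots <- bootstrap_trees(aln, n_reps = 200, seed = 7)
  cons <- majority_rule_consensus(boots)
  sup <- suppressWarnings(as.numeric(cons$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("majority-rule consensus keeps exactly the majority splits", {
  t_ab_cd <- ape::read.tree(text = "((A,B),(C,D),E);")
  t_ab_ce <- ape::read.tree(text = "((A,B),(C,E),D);")
  t_ab_de <- ape::read.tree(text = "((A,B),C,(D,E));")

  # ten identical trees: same topology, all supports 100
  cons10 <- majority_rule_consensus(rep(list(t_ab_cd), 10))
  expect_equal(ape::dist.topo(cons10, t_ab_cd), 0, ignore_attr = TRUE)
  expect_setequal(setdiff(cons10$node.label, ""), "100")

  # a split in 2 of 3 trees survives with support 67
  cons3 <- majority_rule_consensus(list(t_ab_cd, t_ab_cd, t_ab_de))
  expect_true("67" %in% cons3$node.label)
  expect_true("100" %in% cons3$node.label)

  # two incompatible splits at exactly 50% are both dropped
  cons2 <- majority_rule_consensus(list(t_ab_ce, t_ab_de))
  labs <- setdiff(cons2$node.label, "")
  splits_kept <- cons2$Nnode - 1  # non-root internal nodes
  expect_equal(splits_kept, 1)   # only the unanimous (A,B) split remains
  expect_setequal(labs, "100")

  # differing leaf sets are rejected with the difference named
  t_other <- ape::read.tree(text = "((A,B),(C,F),E);")
  expect_error(majority_rule_consensus(list(t_ab_cd, t_other)), "F")
})

test_that("consensus supports are multiples of 100/n and above 50", {
  set.seed(44)
  sim <- generate_alignment(n_leaves = 6, n_columns = 80, rate = 0.6, seed = 11)
  boots <- bootstrap_trees(sim$alignment, n_reps = 25, seed = 3)
  cons <- majority_rule_consensus(boots)
  sup <- suppressWarnings(as.numeric(setdiff(cons$node.label, "")))
  expect_true(all(sup > 50))
})

test_that("genus-specific clades: examples, maximality, and oracle equivalence", {
  tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  res <- genus_specific_clades(tr, map)
  expect_equal(nrow(res$single_group), 2)
  expect_setequal(res$single_group$group, c("A", "B"))

  # nested single-group clades: only the maximal one is reported
  tr2 <- ape::read.tree(text = "(((a1,a2),a3),(b1,b2));")
  map2 <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  res2 <- genus_specific_clades(tr2, map2)
  a_clades <- res2$single_group |> dplyr::filter(group == "A")
  expect_equal(nrow(a_clades), 1)
  expect_equal(a_clades$n_leaves, 3)

  expect_error(genus_specific_clades(tr, map[-1]), "a1")

  set.seed(45)
  for (k in 1:100) {
    n <- sample(5:14, 1)
    tr <- ape::rtree(n, tip.label = sprintf("x%02d", 1:n))
    map <- setNames(sample(c("A", "B", "C"), n, replace = TRUE), tr$tip.label)
    res <- genus_specific_clades(tr, map, min_size = 2)
    got <- lapply(seq_len(nrow(res$single_group)), function(i)
      list(group = res$single_group$group[i],
           leaves = sort(res$single_group$leaves[[i]])))
    got <- got[order(vapply(got, function(h) paste(h$leaves, collapse = ","),
                            character(1)))]
    expect_equal(got, oracle_single_group_clades(tr, map, 2))
  }
})

test_that("single-group clades are invariant to rerooting on multi-group branches", {
  tr <- ape::read.tree(
    text = "((((a1,a2),(b1,b2)),(c1,c2)),((a3,a4),(d1,d2)));")
  map <- c(a1 = "A", a2 = "A", a3 = "A", a4 = "A",
           b1 = "B", b2 = "B", c1 = "C", c2 = "C", d1 = "D", d2 = "D")
  ref <- genus_specific_clades(tr, map)
  key <- function(res) {
    vapply(seq_len(nrow(res$single_group)), function(i)
      paste(res$single_group$group[i],
            paste(sort(res$single_group$leaves[[i]]), collapse = ",")),
      character(1))
  }
  # reroot along branches whose both sides span more than one group
  for (out in list(c("a1", "a2", "b1", "b2"), c("a3", "a4", "d1", "d2"))) {
    rer <- ape::unroot(ape::root(tr, outgroup = out, resolve.root = TRUE))
    expect_setequal(key(genus_specific_clades(rer, map)), key(ref))
  }
})

test_that("clade assignment labels leaves and tests monophyly", {
  tr <- ape::read.tree(text = "(((a1,a2),(a3,a4)),((b1,b2),(c1,c2)));")
  defs <- list(TN1 = c("a1", "a2", "a3", "a4"), CN1 = c("b1", "b2"))
  res <- assign_clades(tr, defs)
  expect_true(all(res$report$monophyletic))
  expect_equal(res$assignments$clade_id[res$assignments$leaf == "a1"], "TN1")
  expect_true(is.na(res$assignments$clade_id[res$assignments$leaf == "c1"]))

  # a definition splitting a cherry is non-monophyletic
  res2 <- assign_clades(tr, list(bad = c("b1", "c1")))
  expect_false(res2$report$monophyletic)
  # cross-check with the independent implementation
  expect_equal(res2$report$monophyletic,
               ape::is.monophyletic(tr, c("b1", "c1")))

  expect_error(assign_clades(tr, list(x = "a1", y = "a1")), "overlap")
})

test_that("a planted multi-clade tree is recovered fully monophyletic", {
  set.seed(47)
  clades <- paste0(rep(c("TN", "CN"), c(6, 5)), c(1:6, 1:5))
  sub_nwk <- vapply(clades, function(cl) {
    n <- sample(3:6, 1)
    sub <- ape::rtree(n, tip.label = sprintf("%s_%02d", cl, seq_len(n)))
    sub(";$", "", ape::write.tree(sub))
  }, character(1))
  tr <- ape::read.tree(text = paste0("(", paste(sub_nwk, collapse = ","), ");"))
  defs <- lapply(setNames(clades, clades), function(cl)
    grep(paste0("^", cl, "_"), tr$tip.label, value = TRUE))
  res <- assign_clades(tr, defs)
  expect_equal(nrow(res$report), 11)
  expect_true(all(res$report$monophyletic))
})
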