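#' Simulate a protein alignment along a tree
#'
#' Evolves gap-free amino-acid sequences along a tree under the Dayhoff
#' model: the root sequence is drawn from the equilibrium frequencies and
#' each site evolves independently down every branch with transition
#' probabilities \eqn{P(t) = e^{Qt}}. Branch lengths are in expected
#' substitutions per site. Deterministic given `seed`.
#'
#' @param n_leaves number of leaves (used when `tree` is NULL; the true
#'   tree is then a random topology with branch lengths scaled by `rate`).
#' @param n_columns alignment length.
#' @param rate mean branch length scaling for the random tree; must be
#'   positive (as it approaches zero all sequences become identical).
#' @param seed integer seed.
#' @param tree optional \code{phylo} tree with branch lengths, used as-is.
#' @return List with `alignment` (named character vector, all rows equal
#'   length) and `tree` (the true tree).
#' @export
generate_alignment <- function(n_leaves = 8, n_columns = 300, rate = 0.5,
                               seed = 1, tree = NULL) {
  assert_that(rate > 0, "rate must be positive")
  model <- dayhoff_model()
  with_seed(derive_seed(seed, 7L), {
    if (is.null(tree)) {
      tree <- ape::rtree(n_leaves, rooted = FALSE,
                         tip.label = sprintf("t%02d", seq_len(n_leaves)))
      # lengths uniform on [0.1, 1] x rate: a floor keeps every internal
      # branch identifiable at moderate alignment lengths
      tree$edge.length <- runif(nrow(tree$edge), 0.1, 1) * rate
    }
    n_tip <- length(tree$tip.label)
    po <- ape::reorder.phylo(tree, "cladewise")
    seqs <- vector("list", n_tip + tree$Nnode)
    root <- n_tip + 1L
    seqs[[root]] <- sample(seq_len(20), n_columns, replace = TRUE,
                           prob = model$pi)
    for (e in seq_len(nrow(po$edge))) {
      parent <- po$edge[e, 1]; child <- po$edge[e, 2]
      t_len <- po$edge.length[e]
      P <- dayhoff_pt(max(t_len, 1e-12), model)
      parent_seq <- seqs[[parent]]
      child_seq <- integer(n_columns)
      for (state in unique(parent_seq)) {
        at <- which(parent_seq == state)
        child_seq[at] <- sample(seq_len(20), length(at), replace = TRUE,
                                prob = P[state, ])
      }
      seqs[[child]] <- child_seq
    }
    alignment <- vapply(seq_len(n_tip), function(i)
      paste(AA_ORDER[seqs[[i]]], collapse = ""), character(1))
    names(alignment) <- tree$tip.label
    list(alignment = alignment, tree = tree)
  })
}
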