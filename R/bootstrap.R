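#' Bootstrap replicate trees from a protein alignment
#'
#' Each replicate resamples alignment columns with replacement, recomputes
#' the pairwise distance matrix under `model`, and runs
#' [neighbor_joining()]. Fully reproducible from `seed`. A replicate whose
#' distance matrix contains saturated pairs is retained (with the ceiling
#' distance) and counted in the `n_saturated_replicates` attribute.
#'
#' @param alignment named character vector of equal-length gapped
#'   amino-acid strings.
#' @param n_reps number of bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param model distance model passed to [protein_distance()].
#' @param resample_fun optional function `(n_columns) -> column indices`,
#'   substituted for the default sampler (used to force, e.g., an identity
#'   resample).
#' @return List of \code{phylo} trees with attribute
#'   `n_saturated_replicates`.
#' @export
bootstrap_trees <- function(alignment, n_reps = 500, seed = 1,
                            model = "dayhoff_ml", resample_fun = NULL) {
  assert_that(length(alignment) >= 3, "alignment must hold at least 3 sequences")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  n_col <- ncol(mat)
  assert_that(n_col >= 1, "alignment is empty")
  n_sat <- 0L
  trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(rep_i) {
      idx <- if (is.null(resample_fun)) {
        sample.int(n_col, n_col, replace = TRUE)
      } else {
        resample_fun(n_col)
      }
      rep_aln <- setNames(apply(mat[, idx, drop = FALSE], 1, paste, collapse = ""),
                          names(alignment))
      dm <- protein_distance(rep_aln, model = model, refine = FALSE)
      if (any(attr(dm, "saturated"))) n_sat <<- n_sat + 1L
      neighbor_joining(dm)
    })
  })
  attr(trees, "n_saturated_replicates") <- n_sat
  trees
}

# Non-trivial splits of a tree as canonical keys. Each internal edge
# defines a bipartition; the side not containing the reference leaf (the
# alphabetically first) is the canonical side, keyed by its sorted leaves.
tree_splits <- function(tree, ref_leaf) {
  n_tip <- length(tree$tip.label)
  desc <- descendant_leaf_sets(tree)
  keys <- character()
  sides <- list()
  for (node in seq(n_tip + 2L, n_tip + tree$Nnode)) {
    leaves <- desc[[node - n_tip]]
    side <- if (ref_leaf %in% leaves) setdiff(tree$tip.label, leaves) else leaves
    if (length(side) < 2 || length(side) > n_tip - 2) next
    key <- paste(sort(side), collapse = "\r")
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      sides[[length(sides) + 1]] <- sort(side)
    }
  }
  setNames(sides, keys)
}

# leaf label sets of every internal node (index 1 = root = n_tip+1)
descendant_leaf_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  sets <- vector("list", n_node)
  edge <- tree$edge
  # postorder: process edges child-first
  po <- ape::reorder.phylo(tree, "postorder")$edge
  acc <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) acc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po))) {
    parent <- po[e, 1]; child <- po[e, 2]
    acc[[parent]] <- c(acc[[parent]], acc[[child]])
  }
  for (v in seq_len(n_node)) sets[[v]] <- acc[[v + n_tip]]
  sets
}

#' Strict majority-rule consensus tree
#'
#' Keeps exactly the splits present in more than half of the input trees
#' (no greedy extension with further compatible splits). Supports are
#' `100 x` the split frequency, rounded to integer, and attach to the
#' child node of each split (Newick node-label convention).
#'
#' @param trees list of \code{phylo} trees sharing one leaf set.
#' @return A \code{phylo} object whose `node.label` holds integer supports
#'   (root label empty).
#' @export
majority_rule_consensus <- function(trees) {
  assert_that(length(trees) >= 1, "need at least one tree")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  base <- leafsets[[1]]
  for (k in seq_along(leafsets)) {
    if (!identical(leafsets[[k]], base)) {
      diff <- c(setdiff(base, leafsets[[k]]), setdiff(leafsets[[k]], base))
      abort(paste0("trees have differing leaf sets; difference: ",
                   paste(unique(diff), collapse = ", ")))
    }
  }
  ref <- base[1]
  n_trees <- length(trees)
  counts <- list()
  for (t in trees) {
    for (key in names(tree_splits(t, ref))) {
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  kept <- names(counts)[vapply(counts, function(x) x > n_trees / 2, logical(1))]
  kept_sides <- lapply(kept, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  support <- vapply(kept, function(k) round(100 * counts[[k]] / n_trees), numeric(1))

  # splits occurring in >50% of trees are pairwise compatible; nest them
  ord <- order(vapply(kept_sides, length, integer(1)))
  kept_sides <- kept_sides[ord]
  support <- support[ord]
  build_nested <- function(leaves, avail) {
    # avail: indices of kept splits whose side is a subset of `leaves`
    direct <- avail[order(-vapply(avail, function(s) length(kept_sides[[s]]),
                                  integer(1)))]
    children <- list()
    used <- character()
    for (s in direct) {
      side <- kept_sides[[s]]
      if (any(side %in% used)) next  # nested inside an already-taken child
      sub <- setdiff(avail, s)
      sub <- sub[vapply(sub, function(x) all(kept_sides[[x]] %in% side), logical(1))]
      node <- build_nested(side, sub)
      node$label <- as.character(support[s])
      children[[length(children) + 1]] <- node
      used <- c(used, side)
    }
    for (leaf in setdiff(leaves, used)) {
      children[[length(children) + 1]] <- list(leaf = leaf)
    }
    list(children = children)
  }
  avail <- seq_along(kept_sides)
  root <- build_nested(base, avail)
  root$label <- ""
  subtree_to_phylo(root, node_labels = TRUE)
}
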