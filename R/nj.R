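#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion. The
#' implementation is deterministic and label-driven: the distance matrix is
#' first reordered by sorted labels and ties in Q are broken towards the
#' lexicographically smallest pair of subtree names (a subtree is named by
#' its smallest leaf label), so the result is invariant to the input label
#' order. Negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch of the same join. The returned tree is
#' unrooted, represented with a trifurcating root.
#'
#' @param dm symmetric numeric matrix with dimnames (or `dist`).
#' @return An `ape` \code{phylo} object.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  labels <- rownames(dm)
  assert_that(!is.null(labels), "distance matrix must have dimnames")
  n <- nrow(dm)
  assert_that(n >= 3, "neighbor joining needs at least 3 taxa")
  ord <- order(labels)
  d <- dm[ord, ord, drop = FALSE]

  nodes <- lapply(labels[ord], function(l) list(leaf = l))
  node_names <- labels[ord]

  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- sort(node_names[ij])
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]

    dij <- d[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    new_node <- list(children = list(nodes[[i]], nodes[[j]]), lens = c(li, lj))
    new_name <- min(node_names[c(i, j)])
    dk <- (d[i, ] + d[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    node_names <- c(node_names[keep], new_name)
  }

  # join the final three nodes at a trifurcating root (three-point formulas)
  l1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  root <- list(children = nodes, lens = c(l1, l2, l3))
  subtree_to_phylo(root)
}

# Convert the recursive subtree structure used by neighbor_joining() /
# majority_rule_consensus() into an ape phylo object.
subtree_to_phylo <- function(root, node_labels = FALSE) {
  tips <- character()
  collect_tips <- function(nd) {
    if (!is.null(nd$leaf)) tips[length(tips) + 1] <<- nd$leaf
    else for (ch in nd$children) collect_tips(ch)
  }
  collect_tips(root)
  n_tip <- length(tips)

  edges <- matrix(0L, 0, 2)
  lens <- numeric()
  labs <- character()
  tip_i <- 0L
  node_i <- n_tip + 1L
  next_node <- n_tip + 1L

  build <- function(nd) {
    if (!is.null(nd$leaf)) {
      tip_i <<- tip_i + 1L
      return(tip_i)
    }
    my_id <- next_node
    next_node <<- next_node + 1L
    labs[my_id - n_tip] <<- if (!is.null(nd$label)) as.character(nd$label) else ""
    for (k in seq_along(nd$children)) {
      child_id <- build(nd$children[[k]])
      edges <<- rbind(edges, c(my_id, child_id))
      lens <<- c(lens, if (!is.null(nd$lens)) nd$lens[k] else NA_real_)
    }
    my_id
  }
  build(root)

  tr <- list(edge = edges, tip.label = tips, Nnode = next_node - n_tip - 1L)
  if (!all(is.na(lens))) tr$edge.length <- lens
  if (node_labels) tr$node.label <- labs
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}
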