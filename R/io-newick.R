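#' Write a tree in Newick format
#'
#' Branch lengths are printed with six decimal places and internal-node
#' bootstrap supports (the `node.label` of the `phylo` object) are written
#' as node labels, so `read_newick(write_newick(t))` recovers the topology,
#' the supports, and branch lengths to within 1e-6.
#'
#' @param tree an `ape` \code{phylo} object with unique leaf labels free of
#'   Newick metacharacters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    abort(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  }
  bad <- grepl("[(),:;\\[\\]\\s]", tree$tip.label, perl = TRUE)
  if (any(bad)) {
    abort(paste0("leaf label contains Newick metacharacters: ",
                 paste(tree$tip.label[bad], collapse = ", ")))
  }
  writeLines(deparse_newick(tree), path)
  invisible(path)
}

# Serialize a phylo object. Kept in-package (rather than ape::write.tree)
# only to pin the branch-length format to six decimals.
deparse_newick <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  node_lab <- tree$node.label
  rec <- function(node, edge_idx) {
    if (node <= n_tip) {
      lab <- tree$tip.label[node]
    } else {
      kids <- children[[as.character(node)]]
      inner <- paste(vapply(kids, function(e) rec(tree$edge[e, 2], e),
                            character(1)), collapse = ",")
      nl <- if (!is.null(node_lab)) {
        l <- node_lab[node - n_tip]
        if (is.na(l)) "" else as.character(l)
      } else ""
      lab <- paste0("(", inner, ")", nl)
    }
    if (has_len && !is.na(edge_idx)) {
      paste0(lab, sprintf(":%.6f", tree$edge.length[edge_idx]))
    } else {
      lab
    }
  }
  paste0(rec(root, NA_integer_), ";")
}

#' Read a tree from a Newick file
#'
#' @param path path to a Newick file.
#' @return An `ape` \code{phylo} object; node labels (bootstrap supports)
#'   are preserved as written.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  assert_that(inherits(tree, "phylo"), paste0("could not parse Newick file: ", path))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    abort(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  }
  tree
}
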