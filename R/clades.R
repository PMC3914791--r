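#' Maximal single-group clades of a labeled tree
#'
#' Given a mapping of every leaf to a group (e.g. a genus), finds every
#' internal node whose descendant leaves all belong to one group, with at
#' least `min_size` leaves, and whose parent's leaf set spans more than one
#' group (maximality; the root qualifies when the whole tree is one
#' group). Also inventories which group combinations occur, counting each
#' combination's maximal clades (nodes whose group set differs from their
#' parent's).
#'
#' The single-group output is invariant to re-rooting along any branch
#' whose both sides contain more than one group.
#'
#' @param tree a \code{phylo} object.
#' @param leaf_groups named character vector mapping every leaf label to a
#'   group, or a two-column tibble/data.frame `(leaf, group)`.
#' @param min_size minimum clade size (default 2).
#' @return List with `single_group` (tibble `group`, `n_leaves`, `leaves`
#'   list-column) and `mixed` (tibble `groups` (comma-joined combination),
#'   `n_clades` over maximal clades of that combination).
#' @export
genus_specific_clades <- function(tree, leaf_groups, min_size = 2) {
  map <- as_group_map(leaf_groups)
  unmapped <- setdiff(tree$tip.label, names(map))
  if (length(unmapped)) {
    abort(paste0("leaves without a group mapping: ",
                 paste(unmapped, collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  desc <- descendant_leaf_sets(tree)
  groups_of <- lapply(desc, function(l) sort(unique(unname(map[l]))))
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]

  single <- list()
  combos <- character()
  for (node in seq_len(tree$Nnode)) {
    node_id <- node + n_tip
    g <- groups_of[[node]]
    size <- length(desc[[node]])
    parent <- parent_of[node_id]
    parent_groups <- if (parent == 0) NULL else groups_of[[parent - n_tip]]
    maximal <- if (parent == 0) TRUE else !identical(g, parent_groups)
    if (!maximal || size < min_size) next
    if (length(g) == 1) {
      single[[length(single) + 1]] <-
        tibble(group = g, n_leaves = size, leaves = list(sort(desc[[node]])))
    } else {
      combos <- c(combos, paste(g, collapse = ","))
    }
  }
  single_tbl <- bind_rows(single)
  if (nrow(single_tbl) == 0) {
    single_tbl <- tibble(group = character(), n_leaves = integer(),
                         leaves = list())
  }
  mixed <- if (length(combos)) {
    tibble(groups = combos) |> count(.data$groups, name = "n_clades")
  } else {
    tibble(groups = character(), n_clades = integer())
  }
  list(single_group = single_tbl, mixed = mixed)
}

as_group_map <- function(leaf_groups) {
  if (is.data.frame(leaf_groups)) {
    setNames(as.character(leaf_groups[[2]]), as.character(leaf_groups[[1]]))
  } else {
    leaf_groups
  }
}

#' Assign predefined clades to tree leaves and test their monophyly
#'
#' Clade boundaries in genome-wide RGA trees are usually drawn by the
#' analyst rather than inferred; this takes those definitions as input.
#' Each listed leaf receives its clade id, and each clade is reported
#' monophyletic when some node's descendant leaf set equals the definition
#' exactly.
#'
#' @param tree a \code{phylo} object.
#' @param clade_definitions named list mapping clade id to a character
#'   vector of leaf labels; definitions must not overlap.
#' @return List with `assignments` (tibble `leaf`, `clade_id`; unlisted
#'   leaves get `NA`) and `report` (tibble `clade_id`, `n_leaves`,
#'   `monophyletic`).
#' @export
assign_clades <- function(tree, clade_definitions) {
  all_leaves <- unlist(clade_definitions, use.names = FALSE)
  dup <- unique(all_leaves[duplicated(all_leaves)])
  if (length(dup)) {
    abort(paste0("overlapping clade definitions; leaves in more than one clade: ",
                 paste(dup, collapse = ", ")))
  }
  missing <- setdiff(all_leaves, tree$tip.label)
  if (length(missing)) {
    abort(paste0("clade definitions name leaves absent from the tree: ",
                 paste(missing, collapse = ", ")))
  }
  desc <- descendant_leaf_sets(tree)
  desc_keys <- vapply(desc, function(l) paste(sort(l), collapse = "\r"),
                      character(1))
  report <- purrr::map_dfr(names(clade_definitions), function(cid) {
    leaves <- sort(clade_definitions[[cid]])
    mono <- length(leaves) == 1 ||
      paste(leaves, collapse = "\r") %in% desc_keys
    tibble(clade_id = cid, n_leaves = length(leaves), monophyletic = mono)
  })
  assign_map <- setNames(rep(names(clade_definitions),
                             lengths(clade_definitions)), all_leaves)
  assignments <- tibble(
    leaf = tree$tip.label,
    clade_id = unname(assign_map[tree$tip.label])
  )
  list(assignments = assignments, report = report)
}
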