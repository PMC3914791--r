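#' Cluster-calling configuration
#'
#' A cluster is two or more RGAs on one chromosome in which every adjacent
#' pair is separated by at most `max_gap` base pairs (measured between the
#' facing interval ends) and by at most `max_intervening` non-RGA open
#' reading frames. The defaults (250 kb, 21 ORFs) follow the classic
#' Arabidopsis-style cluster definition.
#'
#' @param max_gap maximum gap between neighbouring RGA intervals in base
#'   pairs (default 250,000).
#' @param max_intervening maximum count of non-RGA genes strictly between
#'   two neighbouring RGAs (default 21; a 22nd intervening ORF breaks the
#'   chain).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(max_gap = 250000, max_intervening = 21L) {
  assert_that(max_gap > 0, "max_gap must be positive")
  assert_that(max_intervening >= 0, "max_intervening must be >= 0")
  structure(list(max_gap = max_gap, max_intervening = as.integer(max_intervening)),
            class = "cluster_config")
}

#' Call positional RGA clusters on chromosomes
#'
#' Consecutive anchored, non-allele RGAs on a chromosome are chained while
#' both chaining conditions of [cluster_config()] hold; maximal chains of
#' length >= 2 are clusters, the remaining RGAs singletons. The rule is
#' strand-agnostic. Intervening ORFs are genes of the annotation that are
#' not RGAs (alleles count as RGAs, not as intervening ORFs) and lie wholly
#' between the two neighbouring RGA intervals.
#'
#' @param records RGA record tibble; alleles and unanchored records are
#'   ignored for membership.
#' @param annotation `rga_annotation` providing all ORFs for the
#'   intervening-gene counts.
#' @param cfg a [cluster_config()].
#' @return A list of class `rga_clusters`: `clusters` (tibble with
#'   `cluster_id`, `chromosome`, `n_members`, `span_start`, `span_end` and
#'   a `members` list-column of gene ids ordered by start) and `singletons`
#'   (tibble `gene_id`, `chromosome`).
#' @export
call_clusters <- function(records, annotation, cfg = cluster_config()) {
  use <- records |>
    filter(!.data$is_allele, !is.na(.data$chromosome)) |>
    arrange(.data$chromosome, .data$start, .data$gene_id)
  rga_ids <- records$gene_id
  orfs <- annotation$genes |> filter(!(.data$gene_id %in% rga_ids))

  clusters <- list()
  singles <- list()
  for (chr in unique(use$chromosome)) {
    r <- use[use$chromosome == chr, , drop = FALSE]
    o <- orfs[!is.na(orfs$chromosome) & orfs$chromosome == chr, , drop = FALSE]
    k <- nrow(r)
    if (k == 1) {
      singles[[length(singles) + 1]] <- tibble(gene_id = r$gene_id, chromosome = chr)
      next
    }
    chained <- logical(k - 1)
    for (i in seq_len(k - 1)) {
      gap <- r$start[i + 1] - r$end[i]
      n_between <- sum(o$start >= r$end[i] & o$end <= r$start[i + 1])
      chained[i] <- gap <= cfg$max_gap && n_between <= cfg$max_intervening
    }
    run_id <- cumsum(c(0, !chained))
    for (g in split(seq_len(k), run_id)) {
      if (length(g) >= 2) {
        clusters[[length(clusters) + 1]] <- tibble(
          chromosome = chr,
          n_members = length(g),
          span_start = min(r$start[g]),
          span_end = max(r$end[g]),
          members = list(r$gene_id[g])
        )
      } else {
        singles[[length(singles) + 1]] <-
          tibble(gene_id = r$gene_id[g], chromosome = chr)
      }
    }
  }
  cl <- bind_rows(clusters)
  if (nrow(cl) > 0) {
    cl <- cl |>
      arrange(.data$chromosome, .data$span_start) |>
      group_by(.data$chromosome) |>
      mutate(cluster_id = sprintf("%s_c%02d", .data$chromosome, row_number())) |>
      ungroup() |>
      select("cluster_id", "chromosome", "n_members", "span_start",
             "span_end", "members")
  } else {
    cl <- tibble(cluster_id = character(), chromosome = character(),
                 n_members = integer(), span_start = numeric(),
                 span_end = numeric(), members = list())
  }
  sg <- bind_rows(singles)
  if (nrow(sg) == 0) sg <- tibble(gene_id = character(), chromosome = character())
  structure(list(clusters = cl, singletons = sg), class = "rga_clusters")
}

#' Attach cluster ids to RGA records
#'
#' @param records RGA record tibble.
#' @param clusters result of [call_clusters()].
#' @return `records` with `cluster_id` filled for cluster members.
#' @export
assign_cluster_ids <- function(records, clusters) {
  map <- clusters$clusters |>
    select("cluster_id", "members") |>
    tidyr::unnest(cols = "members") |>
    rename(gene_id = "members")
  records$cluster_id <- map$cluster_id[match(records$gene_id, map$gene_id)]
  records
}
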