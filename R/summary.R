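#' Summarise genome organization of an RGA catalog
#'
#' Computes the standard genome-organization summary: per-chromosome RGA,
#' singleton and cluster counts with mean cluster sizes, and catalog-wide
#' totals (anchored and clustered fractions, the share of the six
#' RGA-richest chromosomes, the RGA fraction of all predicted genes, RGA
#' density per megabase, and mean exon counts overall and per superclass).
#'
#' Rounding is fixed so summaries are bit-reproducible: percentages of the
#' predicted-gene count and densities to 2 decimals, mean cluster sizes to
#' 1 decimal, share percentages to whole percent.
#'
#' @param records RGA record tibble; alleles are excluded internally.
#' @param clusters result of [call_clusters()] on the same records.
#' @param n_predicted_genes total number of predicted genes in the genome.
#' @param genome_mb genome size in megabases.
#' @return An object of class `rga_catalog_summary`: list with
#'   `per_chromosome` (tibble), `totals` (one-row tibble) and
#'   `class_counts` (tibble of class/superclass counts).
#' @export
summarize_catalog <- function(records, clusters, n_predicted_genes, genome_mb) {
  assert_that(n_predicted_genes > 0, "n_predicted_genes must be positive")
  recs <- records |> filter(!.data$is_allele)
  anchored <- recs |> filter(!is.na(.data$chromosome))
  cl <- clusters$clusters
  sg <- clusters$singletons

  per_chr <- anchored |>
    count(.data$chromosome, name = "n_rgas") |>
    left_join(sg |> count(.data$chromosome, name = "n_singletons"),
              by = "chromosome") |>
    left_join(cl |>
                group_by(.data$chromosome) |>
                summarise(n_clusters = n(),
                          n_clustered = sum(.data$n_members), .groups = "drop"),
              by = "chromosome") |>
    mutate(
      n_singletons = ifelse(is.na(.data$n_singletons), 0L, .data$n_singletons),
      n_clusters = ifelse(is.na(.data$n_clusters), 0L, .data$n_clusters),
      n_clustered = ifelse(is.na(.data$n_clustered), 0L, .data$n_clustered),
      mean_cluster_size = ifelse(.data$n_clusters > 0,
                                 round(.data$n_clustered / .data$n_clusters, 1), NA_real_),
      share_pct = round(100 * .data$n_rgas / max(nrow(anchored), 1))
    ) |>
    arrange(.data$chromosome)

  n_rgas <- nrow(recs)
  n_anchored <- nrow(anchored)
  n_clustered <- sum(cl$n_members)
  n_clusters <- nrow(cl)
  top6 <- per_chr |> arrange(desc(.data$n_rgas)) |> head(6)

  totals <- tibble(
    n_rgas = n_rgas,
    n_alleles = sum(records$is_allele),
    n_anchored = n_anchored,
    n_unanchored = n_rgas - n_anchored,
    n_singletons = nrow(sg),
    n_clusters = n_clusters,
    n_clustered = n_clustered,
    pct_clustered = if (n_anchored > 0) round(100 * n_clustered / n_anchored) else 0,
    top6_chromosomes = paste(sort(top6$chromosome), collapse = ","),
    top6_share_pct = if (n_anchored > 0) round(100 * sum(top6$n_rgas) / n_anchored) else 0,
    mean_cluster_size = if (n_clusters > 0) round(n_clustered / n_clusters, 1) else NA_real_,
    max_cluster_size = if (n_clusters > 0) max(cl$n_members) else NA_integer_,
    pct_of_predicted_genes = round(100 * n_rgas / n_predicted_genes, 2),
    density_per_mb = if (genome_mb > 0) round(n_rgas / genome_mb, 2) else NA_real_,
    mean_exons = if (n_rgas > 0) round(mean(recs$n_exons), 2) else NA_real_
  )

  class_counts <- recs |>
    count(.data$superclass, .data$class, name = "n") |>
    group_by(.data$superclass) |>
    mutate(superclass_n = sum(.data$n)) |>
    ungroup() |>
    mutate(pct_of_rgas = round(100 * .data$n / max(n_rgas, 1)))

  exons_by_super <- recs |>
    group_by(.data$superclass) |>
    summarise(mean_exons = round(mean(.data$n_exons), 2), .groups = "drop")

  structure(list(per_chromosome = per_chr, totals = totals,
                 class_counts = class_counts, exons_by_superclass = exons_by_super),
            class = "rga_catalog_summary")
}

#' Class-by-chromosome composition of an RGA catalog
#'
#' Cross-tabulates anchored, non-allele records by class (and superclass)
#' and chromosome, with both row-normalized percentages (how a class
#' distributes over chromosomes) and column-normalized percentages (how a
#' chromosome is composed of classes).
#'
#' @param records RGA record tibble.
#' @return List with long tibbles `by_class` and `by_superclass`, columns
#'   `class`/`superclass`, `chromosome`, `n`, `row_pct`, `col_pct`.
#' @export
class_chromosome_crosstab <- function(records) {
  recs <- records |> filter(!.data$is_allele, !is.na(.data$chromosome))
  xt <- function(var) {
    recs |>
      count(.data[[var]], .data$chromosome, name = "n") |>
      group_by(.data[[var]]) |>
      mutate(row_pct = round(100 * .data$n / sum(.data$n), 1)) |>
      ungroup() |>
      group_by(.data$chromosome) |>
      mutate(col_pct = round(100 * .data$n / sum(.data$n), 1)) |>
      ungroup()
  }
  list(by_class = xt("class"), by_superclass = xt("superclass"))
}

#' Compare exon counts between RGA groups
#'
#' Reports group mean exon counts and a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) p-value for the difference. Typical use contrasts the CNL and
#' TNL classes, which differ markedly in exon structure.
#'
#' @param records RGA record tibble.
#' @param groups two group labels to compare (default `c("CNL", "TNL")`).
#' @param by grouping column, `"class"` or `"superclass"`.
#' @return List of class `rga_exon_test` with `means` (tibble of `group`,
#'   `n`, `mean_exons` rounded to 2 decimals), `p_value` (NA when a group
#'   has fewer than 2 members) and `test`.
#' @export
compare_exon_counts <- function(records, groups = c("CNL", "TNL"), by = "class") {
  assert_that(length(groups) == 2, "exactly two groups are compared")
  recs <- records |> filter(!.data$is_allele)
  x <- recs$n_exons[recs[[by]] == groups[1]]
  y <- recs$n_exons[recs[[by]] == groups[2]]
  means <- tibble(group = groups,
                  n = c(length(x), length(y)),
                  mean_exons = round(c(mean(x), mean(y)), 2))
  p <- if (length(x) >= 2 && length(y) >= 2) {
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  } else {
    NA_real_
  }
  structure(list(means = means, p_value = p,
                 test = "Mann-Whitney U (two-sided)"),
            class = "rga_exon_test")
}
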