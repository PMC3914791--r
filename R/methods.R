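#' @export
tidy.rga_catalog_summary <- function(x, ...) x$per_chromosome

#' @export
glance.rga_catalog_summary <- function(x, ...) x$totals

#' @export
tidy.rga_clusters <- function(x, ...) {
  x$clusters |>
    mutate(members = vapply(.data$members, paste, character(1), collapse = ","))
}

#' @export
glance.rga_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_clustered = sum(x$clusters$n_members),
         n_singletons = nrow(x$singletons),
         max_cluster_size = if (nrow(x$clusters)) max(x$clusters$n_members)
                            else NA_integer_)
}

#' @export
tidy.rga_links <- function(x, ...) {
  as_tibble(x) |> select("chr_a", "chr_b", "n_low_ks_pairs", "accepted")
}

#' @export
glance.rga_links <- function(x, ...) {
  tibble(n_links_tested = nrow(x),
         n_accepted = sum(x$accepted),
         n_accepted_inter = sum(x$accepted & x$chr_a != x$chr_b),
         ks_threshold = attr(x, "ks_threshold"))
}

#' @export
tidy.rga_exon_test <- function(x, ...) x$means

#' @export
glance.rga_exon_test <- function(x, ...) {
  tibble(p_value = x$p_value, test = x$test)
}

#' @export
print.rga_catalog_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0(
    "RGA catalog: %d RGAs (%d alleles collapsed), %d anchored\n",
    "  clustered: %d in %d clusters (%d%%), mean size %.1f, largest %d\n",
    "  %.2f%% of predicted genes, %.2f per Mb\n"),
    t$n_rgas, t$n_alleles, t$n_anchored, t$n_clustered, t$n_clusters,
    t$pct_clustered, t$mean_cluster_size, t$max_cluster_size,
    t$pct_of_predicted_genes, t$density_per_mb))
  invisible(x)
}

#' Per-chromosome RGA organization plot
#'
#' Stacked bars of clustered vs singleton RGAs per chromosome.
#'
#' @param object an `rga_catalog_summary`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.rga_catalog_summary <- function(object, ...) {
  df <- object$per_chromosome |>
    select("chromosome", clustered = "n_clustered",
           singleton = "n_singletons") |>
    tidyr::pivot_longer(c("clustered", "singleton"),
                        names_to = "organization", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome, y = .data$n,
                                   fill = .data$organization)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "RGAs",
                  title = "RGA organization per chromosome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ks distribution plot
#'
#' Histogram of defined pairwise Ks values with the link threshold marked;
#' the mass below the threshold drives chromosome-connection calls.
#'
#' @param estimates tibble from [all_pairs_ks()].
#' @param threshold Ks cutoff drawn as a vertical line (default 0.25).
#' @param binwidth histogram bin width.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(estimates, threshold = 0.25, binwidth = 0.05) {
  df <- estimates |> filter(!is.na(.data$ks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Ks (synonymous substitutions per site)", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Class-by-chromosome composition plot
#'
#' @param records RGA record tibble.
#' @return A ggplot object.
#' @export
plot_class_composition <- function(records) {
  xt <- class_chromosome_crosstab(records)$by_superclass
  ggplot2::ggplot(xt, ggplot2::aes(x = .data$chromosome, y = .data$col_pct,
                                   fill = .data$superclass)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of chromosome's RGAs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
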