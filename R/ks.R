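#' Chromosome-link configuration
#'
#' A connection between two chromosomes is accepted when at least
#' `min_pairs` RGA pairs between them have a defined Ks lower than or equal
#' to `ks_threshold`. The defaults (0.25, 10) correspond to the first
#' quartile of genome-wide RGA Ks distributions commonly used to isolate
#' recent duplications.
#'
#' @param ks_threshold Ks cutoff (default 0.25); set `NA` to use the
#'   empirical first quartile of the defined Ks values instead.
#' @param min_pairs minimum number of qualifying pairs (default 10).
#' @return A list of class `link_config`.
#' @export
link_config <- function(ks_threshold = 0.25, min_pairs = 10L) {
  assert_that(is.na(ks_threshold) || ks_threshold > 0,
              "ks_threshold must be positive (or NA for empirical quartile)")
  assert_that(min_pairs >= 1, "min_pairs must be >= 1")
  structure(list(ks_threshold = ks_threshold, min_pairs = as.integer(min_pairs)),
            class = "link_config")
}

#' Enumerate RGA pairs in scope for Ks estimation
#'
#' One row per unordered pair of non-allele RGAs; with
#' `scope = "anchored_only"` (default) only chromosome-anchored records
#' enter, so the pair count is `n(n-1)/2` over the anchored set. The output
#' is ordered by `(gene_a, gene_b)` with `gene_a < gene_b`, independent of
#' the input record order.
#'
#' @param records RGA record tibble.
#' @param scope `"anchored_only"` or `"all"`.
#' @return Tibble with `gene_a`, `gene_b`.
#' @export
ks_pairs <- function(records, scope = c("anchored_only", "all")) {
  scope <- match.arg(scope)
  recs <- records |> filter(!.data$is_allele)
  if (scope == "anchored_only") recs <- recs |> filter(!is.na(.data$chromosome))
  ids <- sort(recs$gene_id)
  if (length(ids) < 2) return(tibble(gene_a = character(), gene_b = character()))
  cmb <- combn(ids, 2)
  tibble(gene_a = cmb[1, ], gene_b = cmb[2, ]) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Pairwise Ks estimates over an RGA catalog
#'
#' For every pair in scope, globally aligns the two proteins, threads the
#' CDS onto the alignment ([codon_align()]) and applies [ng86()]. Proteins
#' are translated from the CDS when not supplied.
#'
#' @param records RGA record tibble.
#' @param cds named character vector of coding sequences; required for
#'   every record in scope.
#' @param proteins optional named character vector of protein sequences.
#' @param scope `"anchored_only"` or `"all"`.
#' @return Tibble with `gene_a`, `gene_b` and the [ng86()] columns.
#' @export
all_pairs_ks <- function(records, cds, proteins = NULL,
                         scope = c("anchored_only", "all")) {
  scope <- match.arg(scope)
  pairs <- ks_pairs(records, scope)
  if (nrow(pairs) == 0) {
    return(bind_cols(pairs, ng86("", "") |> dplyr::slice(0)))
  }
  in_scope <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- in_scope[!(in_scope %in% names(cds))]
  if (length(missing)) {
    abort(paste0("missing CDS for gene(s): ", paste(missing, collapse = ", ")))
  }
  prot_of <- function(id) {
    p <- proteins[[id]] %||% translate_cds(cds[[id]])
    sub("\\*$", "", p)
  }
  prots <- setNames(vapply(in_scope, prot_of, character(1)), in_scope)

  est <- lapply(seq_len(nrow(pairs)), function(k) {
    pa <- prots[[pairs$gene_a[k]]]
    pb <- prots[[pairs$gene_b[k]]]
    aln <- if (pa == pb) list(a = pa, b = pb) else align_protein_pair(pa, pb)
    ca <- codon_align(aln$a, aln$b,
                      cds[[pairs$gene_a[k]]], cds[[pairs$gene_b[k]]])
    ng86_core(ca$a, ca$b)
  })
  cols <- names(est[[1]])
  est_tbl <- as_tibble(lapply(setNames(cols, cols), function(cn)
    vapply(est, `[[`, if (cn %in% c("n_codons")) integer(1) else
      if (cn == "flags") character(1) else numeric(1), cn)))
  bind_cols(pairs, est_tbl)
}

#' Detect chromosome connections from low-Ks RGA pairs
#'
#' Pairs with defined Ks at or below the threshold are grouped by unordered
#' chromosome pair — including self-pairs, which capture intra-chromosome
#' (tandem) duplication — and a connection is accepted when the group holds
#' at least `cfg$min_pairs` pairs. Accepted inter-chromosome connections
#' are the signature of recent whole-genome-duplication doublets.
#'
#' @param estimates tibble from [all_pairs_ks()].
#' @param records RGA record tibble (provides the chromosome of each gene).
#' @param cfg a [link_config()].
#' @return Tibble of class `rga_links`: `chr_a`, `chr_b` (sorted within
#'   row), `n_low_ks_pairs`, `accepted`, `pairs` list-column. The Ks
#'   threshold actually used is attached as attribute `ks_threshold`.
#' @export
chromosome_links <- function(estimates, records, cfg = link_config()) {
  chr_of <- setNames(records$chromosome, records$gene_id)
  threshold <- cfg$ks_threshold
  if (is.na(threshold)) {
    threshold <- stats::quantile(estimates$ks, 0.25, na.rm = TRUE, names = FALSE)
  }
  qual <- estimates |>
    filter(!is.na(.data$ks), .data$ks <= threshold) |>
    mutate(ca = unname(chr_of[.data$gene_a]),
           cb = unname(chr_of[.data$gene_b])) |>
    filter(!is.na(.data$ca), !is.na(.data$cb)) |>
    mutate(chr_a = pmin(.data$ca, .data$cb),
           chr_b = pmax(.data$ca, .data$cb))
  links <- qual |>
    group_by(.data$chr_a, .data$chr_b) |>
    summarise(
      n_low_ks_pairs = n(),
      pairs = list(dplyr::pick("gene_a", "gene_b", "ks")),
      .groups = "drop"
    ) |>
    mutate(accepted = .data$n_low_ks_pairs >= cfg$min_pairs) |>
    select("chr_a", "chr_b", "n_low_ks_pairs", "accepted", "pairs") |>
    arrange(.data$chr_a, .data$chr_b)
  structure(links, class = c("rga_links", class(links)),
            ks_threshold = threshold)
}

#' First quartile of the defined Ks values
#' @param estimates tibble from [all_pairs_ks()].
#' @return Numeric scalar.
#' @export
ks_first_quartile <- function(estimates) {
  stats::quantile(estimates$ks, 0.25, na.rm = TRUE, names = FALSE)
}
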