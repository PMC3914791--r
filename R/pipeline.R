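#' Run the full RGA analysis pipeline
#'
#' Wires the stages in dependency order: read inputs, promote NB-ARC genes
#' to RGAs and classify architectures, collapse alleles, call clusters,
#' summarize the catalog, build the NBS-domain phylogeny (point estimate,
#' bootstrap, majority-rule consensus), estimate pairwise Ks and detect
#' chromosome connections. All outputs are TSV/Newick/JSON files in
#' `out_dir`; a `manifest.json` records parameters, seed and input/output
#' checksums, so a rerun with identical inputs and seed is byte-identical.
#'
#' The NBS alignment is taken from `alignment` (aligned FASTA) when given;
#' otherwise the NB-ARC hit regions are extracted from the proteins and
#' used directly when they all have equal length (as synthetic data
#' guarantees).
#'
#' @param gff,proteins,cds,hits input file paths (GFF3, FASTA, FASTA,
#'   domain-hit TSV).
#' @param out_dir output directory.
#' @param alignment optional aligned FASTA of NBS domains.
#' @param coil a [coil_config()].
#' @param cluster a [cluster_config()].
#' @param link a [link_config()].
#' @param n_predicted_genes,genome_mb totals for the summary; default to
#'   the annotation's own gene count and sequence lengths.
#' @param bootstrap_reps bootstrap replicates (default 500).
#' @param seed integer seed for the bootstrap.
#' @param scope Ks pair scope, `"anchored_only"` or `"all"`.
#' @param similarity_threshold allele similarity threshold.
#' @return Invisibly, a list with all in-memory results plus `files`.
#' @export
run_pipeline <- function(gff, proteins, cds, hits, out_dir,
                         alignment = NULL,
                         coil = coil_config(), cluster = cluster_config(),
                         link = link_config(),
                         n_predicted_genes = NULL, genome_mb = NULL,
                         bootstrap_reps = 500, seed = 1,
                         scope = "anchored_only",
                         similarity_threshold = 0.90) {
  for (f in c(gff, proteins, cds, hits, alignment)) {
    if (!file.exists(f)) abort(paste0("input file missing: ", f))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, " failed: ", conditionMessage(e)))
    })
  }

  ann <- stage("read", read_gff3(gff))
  prot <- stage("read", read_fasta(proteins, "protein"))
  cds_seq <- stage("read", read_fasta(cds, "nucleotide"))
  hit_tbl <- stage("read", read_domain_hits(hits))
  n_pred <- n_predicted_genes %||% nrow(ann$genes)
  gmb <- genome_mb %||% ann$genome_mb

  records <- stage("classify", promote_to_rga(ann, hit_tbl, prot, coil))
  records <- stage("alleles",
                   collapse_alleles(records, prot, similarity_threshold))
  clusters <- stage("clusters", call_clusters(records, ann, cluster))
  records <- assign_cluster_ids(records, clusters)
  summary <- stage("summarize",
                   summarize_catalog(records, clusters, n_pred, gmb))
  crosstab <- stage("crosstab", class_chromosome_crosstab(records))

  keep <- records |> filter(!.data$is_allele)
  phylo_res <- stage("phylo", {
    aln <- if (!is.null(alignment)) {
      read_fasta(alignment, "protein")
    } else {
      extract_nbs_alignment(keep, hit_tbl, prot)
    }
    point <- neighbor_joining(protein_distance(aln, model = "dayhoff_ml"))
    boots <- bootstrap_trees(aln, n_reps = bootstrap_reps, seed = seed,
                             model = "dayhoff_ml")
    cons <- majority_rule_consensus(boots)
    list(alignment = aln, tree = point, consensus = cons)
  })

  ks_res <- stage("ks", all_pairs_ks(keep, cds_seq, prot, scope = scope))
  links <- stage("links", chromosome_links(ks_res, records, link))

  files <- stage("write", {
    params <- list(
      coil = unclass(coil[c("window", "threshold")]),
      cluster = unclass(cluster), link = unclass(link),
      bootstrap_reps = bootstrap_reps, seed = seed, scope = scope,
      similarity_threshold = similarity_threshold)
    f <- c(
      records = write_stage_tsv(
        records |> select(-"clade_id"), file.path(out_dir, "records.tsv"),
        "classify+alleles+clusters", params),
      clusters = write_stage_tsv(
        clusters$clusters |>
          mutate(members = vapply(.data$members, paste, character(1),
                                  collapse = ",")),
        file.path(out_dir, "clusters.tsv"), "clusters", params),
      summary = write_stage_tsv(summary$totals,
                                file.path(out_dir, "summary.tsv"),
                                "summarize", params),
      per_chromosome = write_stage_tsv(summary$per_chromosome,
                                       file.path(out_dir, "per_chromosome.tsv"),
                                       "summarize", params),
      crosstab = write_stage_tsv(crosstab$by_class,
                                 file.path(out_dir, "crosstab.tsv"),
                                 "crosstab", params),
      ks = write_stage_tsv(ks_res, file.path(out_dir, "ks.tsv"), "ks", params),
      links = write_stage_tsv(
        tidy_links(links), file.path(out_dir, "links.tsv"), "links", params),
      tree = write_newick(phylo_res$tree, file.path(out_dir, "tree.nwk")),
      consensus = write_newick(phylo_res$consensus,
                               file.path(out_dir, "consensus.nwk")))
    inputs <- c(gff = gff, proteins = proteins, cds = cds, hits = hits)
    manifest <- list(
      package = "rgatools",
      version = as.character(utils::packageVersion("rgatools")),
      parameters = params,
      inputs = as.list(tools::md5sum(inputs)),
      outputs = as.list(tools::md5sum(unlist(f))))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    c(f, manifest = manifest_path)
  })

  invisible(list(records = records, clusters = clusters, summary = summary,
                 crosstab = crosstab, phylo = phylo_res, ks = ks_res,
                 links = links, files = files))
}

# Extract the NB-ARC hit region of each protein; usable directly as an
# alignment when all regions have equal length.
extract_nbs_alignment <- function(records, hits, proteins) {
  nbs <- hits |>
    filter(.data$domain == "NB-ARC", .data$gene_id %in% records$gene_id) |>
    group_by(.data$gene_id) |>
    dplyr::slice_min(.data$aa_start, n = 1, with_ties = FALSE) |>
    ungroup()
  segs <- setNames(
    substr(proteins[nbs$gene_id], nbs$aa_start + 1, nbs$aa_end),
    nbs$gene_id)
  if (length(unique(nchar(segs))) != 1) {
    abort(paste0("NB-ARC regions are not equal-length; supply a precomputed ",
                 "NBS alignment (aligned FASTA)"))
  }
  segs
}

# TSV with a '# stage: ...' header comment naming the producing stage and
# parameters; readable back with read_tsv(comment = "#").
write_stage_tsv <- function(tbl, path, stage_name, params) {
  hdr <- sprintf("# stage: %s | rgatools | %s", stage_name,
                 jsonlite::toJSON(params, auto_unbox = TRUE))
  writeLines(hdr, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, progress = FALSE)
  path
}

tidy_links <- function(links) {
  as_tibble(links) |>
    mutate(n_pairs = .data$n_low_ks_pairs) |>
    select("chr_a", "chr_b", "n_pairs", "accepted")
}
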