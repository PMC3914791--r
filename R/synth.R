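# Sentinel 12-mer tags marking each domain in synthetic proteins. Drawn
# from coil-neutral residues so only deliberately planted heptad segments
# trigger the coiled-coil scorer; the domain-hit table is generated from
# the known tag positions, mimicking a profile-HMM search result.
DOMAIN_TAGS <- c(
  "TIR"    = "WDHNGTSPDNGH",
  "NB-ARC" = "HGDSNPWTGHDS",
  "LRR"    = "NPGDSHTWNSGD",
  "BED"    = "GWSTDNHPGSTD",
  "kinase" = "SDGHNTWPSDGH"
)

# Residues with low coiled-coil propensity at every heptad position; used
# for linkers and domain-body filler so random sequence never scores as CC.
LOW_COIL_AA <- c("D", "N", "G", "S", "T", "H", "P", "W", "C", "F", "V", "R", "Y")

# One idealized heptad (positions a-g): hydrophobic core at a/d, charged
# residues at e/g. Five tandem copies score well above the 0.9 threshold.
COIL_HEPTAD <- "LEALEGK"

#' Configuration for the synthetic genome generator
#'
#' The generator emulates the statistical structure of a real RGA
#' catalog: clustered RGA placement among non-RGA ORFs, tandem duplicates
#' with low synonymous divergence, whole-genome-duplication chromosome
#' doublets with a controlled Ks mode, allele pairs duplicated on
#' unplaced scaffolds, chromosome-biased TIR vs non-TIR composition, and
#' proteins with planted domain orders and coiled-coil heptads.
#'
#' Defaults describe a compact genome with one 2-, one 4- and one
#' 21-member cluster (the last mirroring the largest cluster observed in
#' apple), four WGD doublets with Ks modes near 0.15, and one chromosome
#' carrying almost exclusively non-TIR RGAs.
#'
#' @param seed master seed; every output stream derives from it.
#' @param n_chromosomes number of chromosomes (named `Chr01`, ...).
#' @param chromosome_length length of each chromosome in base pairs.
#' @param n_background_genes extra non-RGA ORFs distributed over the
#'   genome in addition to the intervening ORFs placed inside and between
#'   clusters.
#' @param cluster_spec tibble with columns `chromosome`, `n_members`,
#'   `spacing` (bp between consecutive member intervals), `intervening`
#'   (non-RGA ORFs between consecutive members).
#' @param n_singleton_rgas isolated RGAs spread round-robin over
#'   chromosomes.
#' @param allele_spec list `n_pairs`, `similarity`: overlapping duplicate
#'   gene pairs on unplaced scaffolds at the given protein similarity.
#' @param wgd_spec tibble `chr_a`, `chr_b`, `n_pairs`, `target_ks`:
#'   chromosome doublets; each pair is a gene duplicated across the two
#'   chromosomes with synonymous-only divergence raised to `target_ks`.
#' @param class_bias named list mapping chromosome to superclass
#'   proportions `c("TIR-NBS", "non-TIR-NBS-LRR", "other")`; chromosomes
#'   not listed use `default_class_mix`.
#' @param default_class_mix superclass proportions used where no bias is
#'   given.
#' @param coil_fraction fraction of non-TIR RGAs receiving a planted
#'   heptad segment (turning NL into CNL and N into CN).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(
    seed = 1,
    n_chromosomes = 8,
    chromosome_length = 6e6,
    n_background_genes = 150,
    cluster_spec = tibble(
      chromosome = c("Chr01", "Chr02", "Chr02"),
      n_members = c(2L, 4L, 21L),
      spacing = c(20000, 20000, 20000),
      intervening = c(5L, 5L, 3L)
    ),
    n_singleton_rgas = 16,
    allele_spec = list(n_pairs = 4, similarity = 0.96),
    wgd_spec = tibble(
      chr_a = c("Chr01", "Chr02", "Chr03", "Chr04"),
      chr_b = c("Chr05", "Chr06", "Chr07", "Chr08"),
      n_pairs = c(12L, 12L, 12L, 12L),
      target_ks = c(0.12, 0.15, 0.18, 0.15)
    ),
    class_bias = list(
      Chr03 = c("TIR-NBS" = 0.01, "non-TIR-NBS-LRR" = 0.99, "other" = 0)
    ),
    default_class_mix = c("TIR-NBS" = 0.27, "non-TIR-NBS-LRR" = 0.58,
                          "other" = 0.15),
    coil_fraction = 0.5) {
  chroms <- sprintf("Chr%02d", seq_len(n_chromosomes))
  used <- unique(c(cluster_spec$chromosome, wgd_spec$chr_a, wgd_spec$chr_b,
                   names(class_bias)))
  assert_that(all(used %in% chroms),
              "cluster_spec/wgd_spec/class_bias reference undeclared chromosomes")
  assert_that(all(wgd_spec$target_ks < 0.75), "target Ks must be < 0.75")
  mixes <- c(list(default_class_mix), unname(class_bias))
  assert_that(all(abs(vapply(mixes, sum, numeric(1)) - 1) < 1e-8),
              "class proportions must sum to 1")
  structure(list(
    seed = seed, n_chromosomes = n_chromosomes, chromosomes = chroms,
    chromosome_length = chromosome_length,
    n_background_genes = n_background_genes, cluster_spec = cluster_spec,
    n_singleton_rgas = n_singleton_rgas, allele_spec = allele_spec,
    wgd_spec = wgd_spec, class_bias = class_bias,
    default_class_mix = default_class_mix, coil_fraction = coil_fraction
  ), class = "synth_config")
}

rand_aa <- function(n, alphabet = LOW_COIL_AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Build an RGA protein for a class label: ordered sentinel domain segments
# joined by linkers, with a heptad block where the class carries C.
# Returns the protein, the domain-hit intervals (0-based half-open residue
# coordinates) and the true class.
make_rga_protein <- function(class) {
  tokens <- strsplit(class, "")[[1]]
  parts <- list(rand_aa(12))
  hits <- list()
  for (tok in tokens) {
    at <- sum(nchar(unlist(parts)))
    if (tok == "T") {
      seg <- paste0(DOMAIN_TAGS[["TIR"]], rand_aa(24))
      hits[[length(hits) + 1]] <- tibble(domain = "TIR", aa_start = at,
                                         aa_end = at + nchar(seg))
    } else if (tok == "N") {
      seg <- paste0(DOMAIN_TAGS[["NB-ARC"]], rand_aa(48))
      hits[[length(hits) + 1]] <- tibble(domain = "NB-ARC", aa_start = at,
                                         aa_end = at + nchar(seg))
    } else if (tok == "L") {
      seg <- paste0(DOMAIN_TAGS[["LRR"]], rand_aa(28))
      hits[[length(hits) + 1]] <- tibble(domain = "LRR", aa_start = at,
                                         aa_end = at + nchar(seg))
    } else if (tok == "C") {
      seg <- strrep(COIL_HEPTAD, 5)  # detected by scoring, no hit row
    } else {
      abort(paste0("unknown class token: ", tok))
    }
    parts <- c(parts, seg, rand_aa(8))
  }
  list(protein = paste(unlist(parts), collapse = ""),
       hits = bind_rows(hits), class = class)
}

# Reverse-translate a protein with uniformly sampled synonymous codons and
# a terminal stop.
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(r) {
    opts <- by_aa[[r]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

# Apply synonymous-only substitutions to a CDS until the NG86 divergence
# from the original reaches target_ks. Returns the mutated CDS and the
# achieved Ks.
mutate_synonymous <- function(cds, target_ks) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  body <- seq_len(length(codons) - 1L)  # keep the stop codon fixed
  achieved <- 0
  guard <- 0
  repeat {
    for (k in seq_len(5)) {
      i <- sample(body, 1)
      opts <- setdiff(by_aa[[gc[[codons[i]]]]], codons[i])
      if (length(opts)) codons[i] <- opts[sample.int(length(opts), 1)]
    }
    mut <- paste(codons, collapse = "")
    achieved <- ng86(substr(cds, 1, nchar(cds) - 3),
                     substr(mut, 1, nchar(mut) - 3))$ks
    guard <- guard + 1
    if (!is.na(achieved) && achieved >= target_ks) break
    if (guard > 2000) abort("mutate_synonymous failed to reach target Ks")
  }
  list(cds = paste(codons, collapse = ""), ks = achieved)
}

pick_class <- function(chromosome, cfg) {
  mix <- cfg$class_bias[[chromosome]] %||% cfg$default_class_mix
  super <- sample(names(mix), 1, prob = mix)
  if (super == "TIR-NBS") {
    base <- sample(c("TNL", "TN", "NLT"), 1, prob = c(0.7, 0.2, 0.1))
    list(class = base, coil = FALSE)
  } else if (super == "non-TIR-NBS-LRR") {
    coil <- runif(1) < cfg$coil_fraction
    list(class = if (coil) "CNL" else "NL", coil = coil)
  } else {
    coil <- runif(1) < cfg$coil_fraction
    list(class = if (coil) "CN" else "N", coil = coil)
  }
}

sample_exons <- function(superclass) {
  if (identical(superclass, "TIR-NBS")) sample(4:9, 1) else sample(1:6, 1)
}

#' Generate a synthetic genome with ground truth
#'
#' Emits a complete, internally consistent data set — gene models, protein
#' and CDS sequences, a domain-hit table — together with the ground truth
#' of every planted feature, deterministically from `cfg$seed`. See
#' [synth_config()] for what is planted.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional directory; when given, all files are written
#'   there via [write_genome()].
#' @return A list of class `synth_genome`: `annotation`
#'   (`rga_annotation`), `proteins`, `cds` (named character vectors),
#'   `hits` (tibble), and `truth` (list with `genes` tibble and `links`
#'   tibble of planted low-Ks chromosome connections).
#' @export
generate_genome <- function(cfg, out_dir = NULL) {
  assert_that(inherits(cfg, "synth_config"), "cfg must be a synth_config")
  genes <- list(); proteins <- list(); cds <- list(); hits <- list()
  truth <- list()
  cursor <- setNames(rep(50000, cfg$n_chromosomes), cfg$chromosomes)
  counter <- 0L

  next_id <- function(prefix) {
    counter <<- counter + 1L
    sprintf("%s%05d", prefix, counter)
  }
  place <- function(chrom, len, gap_after) {
    start <- cursor[[chrom]]
    if (start + len > cfg$chromosome_length) {
      abort(paste0("infeasible placement: chromosome ", chrom,
                   " cannot hold more genes"))
    }
    cursor[[chrom]] <<- start + len + gap_after
    c(start = start, end = start + len)
  }
  add_background <- function(chrom, gap_after = 200) {
    id <- next_id("bg")
    prot <- rand_aa(sample(80:140, 1),
                    alphabet = rownames(coils_propensity_table()))
    len <- (nchar(prot) + 1) * 3
    pos <- place(chrom, len, gap_after)
    genes[[id]] <<- tibble(gene_id = id, scaffold = chrom, chromosome = chrom,
                           start = pos[["start"]], end = pos[["end"]],
                           strand = sample(c("+", "-"), 1),
                           n_exons = sample(1:10, 1))
    proteins[[id]] <<- prot
    cds[[id]] <<- reverse_translate(prot)
    truth[[id]] <<- tibble(gene_id = id, kind = "background",
                           chromosome = chrom, true_class = NA_character_,
                           coil_planted = FALSE, planted_cluster = NA_character_,
                           allele_partner = NA_character_,
                           wgd_partner = NA_character_, planted_ks = NA_real_)
    id
  }
  add_rga <- function(chrom, made, gap_after, kind = "rga",
                      planted_cluster = NA_character_, cds_override = NULL,
                      protein_override = NULL, wgd_partner = NA_character_,
                      planted_ks = NA_real_, scaffold = chrom,
                      start_override = NULL) {
    id <- next_id("rga")
    prot <- protein_override %||% made$protein
    this_cds <- cds_override %||% reverse_translate(prot)
    len <- nchar(this_cds)
    if (is.null(start_override)) {
      pos <- place(scaffold, len, gap_after)
    } else {
      pos <- c(start = start_override, end = start_override + len)
    }
    super <- class_superclass(made$class)
    genes[[id]] <<- tibble(gene_id = id, scaffold = scaffold,
                           chromosome = if (grepl("^Chr", scaffold)) scaffold
                                        else NA_character_,
                           start = pos[["start"]], end = pos[["end"]],
                           strand = sample(c("+", "-"), 1),
                           n_exons = sample_exons(super))
    proteins[[id]] <<- prot
    cds[[id]] <<- this_cds
    h <- made$hits
    if (nrow(h) > 0) {
      hits[[id]] <<- h |> mutate(gene_id = id, score = round(runif(n(), 30, 200), 1)) |>
        select("gene_id", "domain", "aa_start", "aa_end", "score")
    }
    truth[[id]] <<- tibble(gene_id = id, kind = kind,
                           chromosome = if (grepl("^Chr", scaffold)) scaffold
                                        else NA_character_,
                           true_class = made$class,
                           coil_planted = grepl("C", made$class),
                           planted_cluster = planted_cluster,
                           allele_partner = NA_character_,
                           wgd_partner = wgd_partner, planted_ks = planted_ks)
    id
  }
  separator <- function(chrom) {
    # break any chain: a gap wider than any plausible max_gap setting
    cursor[[chrom]] <<- cursor[[chrom]] + 300000
    add_background(chrom)
  }

  with_seed(derive_seed(cfg$seed, 1L), {
    # --- clusters: tandem families with low synonymous divergence --------
    for (r in seq_len(nrow(cfg$cluster_spec))) {
      spec <- cfg$cluster_spec[r, ]
      chrom <- spec$chromosome
      cl_id <- sprintf("planted_%s_%d", chrom, r)
      cls <- pick_class(chrom, cfg)
      made <- make_rga_protein(cls$class)
      base_cds <- reverse_translate(made$protein)
      for (m in seq_len(spec$n_members)) {
        member_cds <- if (m == 1) base_cds else
          mutate_synonymous(base_cds, 0.03)$cds
        add_rga(chrom, made, gap_after = 500, kind = "cluster_member",
                planted_cluster = cl_id, cds_override = member_cds)
        if (m < spec$n_members) {
          for (k in seq_len(spec$intervening)) add_background(chrom)
          cursor[[chrom]] <- cursor[[chrom]] +
            max(0, spec$spacing - spec$intervening * 700 - 1000)
        }
      }
      separator(chrom)
    }

    # --- WGD doublets ----------------------------------------------------
    for (r in seq_len(nrow(cfg$wgd_spec))) {
      spec <- cfg$wgd_spec[r, ]
      for (p in seq_len(spec$n_pairs)) {
        cls <- pick_class(spec$chr_a, cfg)
        made <- make_rga_protein(cls$class)
        cds_a <- reverse_translate(made$protein)
        mut <- mutate_synonymous(cds_a, spec$target_ks)
        id_a <- add_rga(spec$chr_a, made, gap_after = 0, kind = "wgd",
                        cds_override = cds_a)
        id_b <- add_rga(spec$chr_b, made, gap_after = 0, kind = "wgd",
                        cds_override = mut$cds, wgd_partner = id_a,
                        planted_ks = mut$ks)
        truth[[id_a]]$wgd_partner <- id_b
        truth[[id_a]]$planted_ks <- mut$ks
        separator(spec$chr_a)
        separator(spec$chr_b)
      }
    }

    # --- singleton RGAs --------------------------------------------------
    for (s in seq_len(cfg$n_singleton_rgas)) {
      chrom <- cfg$chromosomes[(s - 1) %% cfg$n_chromosomes + 1]
      cls <- pick_class(chrom, cfg)
      made <- make_rga_protein(cls$class)
      add_rga(chrom, made, gap_after = 0, kind = "singleton")
      separator(chrom)
    }

    # --- remaining background genes --------------------------------------
    for (b in seq_len(cfg$n_background_genes)) {
      chrom <- cfg$chromosomes[(b - 1) %% cfg$n_chromosomes + 1]
      add_background(chrom, gap_after = 3000)
    }

    # --- allele pairs on unplaced scaffolds ------------------------------
    for (a in seq_len(cfg$allele_spec$n_pairs)) {
      scaf <- sprintf("S%03d", a)
      cursor[[scaf]] <- 1000
      cls <- pick_class(cfg$chromosomes[1], cfg)
      # allele pairs use coil-free architectures so that similarity
      # mutations in linkers cannot disturb a planted heptad
      made <- make_rga_protein(gsub("C", "", cls$class))
      id_a <- add_rga(scaf, made, gap_after = 0, kind = "allele_rep",
                      scaffold = scaf)
      # partner: overlap the first gene, substitute linker residues to
      # reach the requested similarity
      prot <- made$protein
      n_mut <- max(1L, round(nchar(prot) * (1 - cfg$allele_spec$similarity)))
      mutable <- setdiff(seq_len(nchar(prot)),
                         unlist(purrr::map2(made$hits$aa_start + 1,
                                            made$hits$aa_end, seq)))
      pos <- sample(mutable, min(n_mut, length(mutable)))
      pchars <- strsplit(prot, "")[[1]]
      for (i in pos) pchars[i] <- sample(setdiff(LOW_COIL_AA, pchars[i]), 1)
      prot_b <- paste(pchars, collapse = "")
      start_b <- genes[[id_a]]$start + round(nchar(cds[[id_a]]) / 2)
      id_b <- add_rga(scaf, made, gap_after = 0, kind = "allele",
                      protein_override = prot_b, scaffold = scaf,
                      start_override = start_b)
      truth[[id_a]]$allele_partner <- id_b
      truth[[id_b]]$allele_partner <- id_a
    }
  })

  # planted self-links from tandem clusters
  self_links <- cfg$cluster_spec |>
    group_by(.data$chromosome) |>
    summarise(n_pairs_planted = sum(choose(.data$n_members, 2)),
              .groups = "drop") |>
    mutate(chr_a = .data$chromosome, chr_b = .data$chromosome,
           source = "tandem_cluster") |>
    select("chr_a", "chr_b", "n_pairs_planted", "source")
  wgd_links <- if (nrow(cfg$wgd_spec) > 0) {
    cfg$wgd_spec |>
      mutate(chr_a2 = pmin(.data$chr_a, .data$chr_b),
             chr_b2 = pmax(.data$chr_a, .data$chr_b)) |>
      select(chr_a = "chr_a2", chr_b = "chr_b2",
             n_pairs_planted = "n_pairs") |>
      mutate(source = "wgd_doublet")
  } else {
    tibble(chr_a = character(), chr_b = character(),
           n_pairs_planted = integer(), source = character())
  }

  genes_tbl <- bind_rows(genes) |> arrange(.data$scaffold, .data$start)
  seqlens <- setNames(rep(cfg$chromosome_length, cfg$n_chromosomes),
                      cfg$chromosomes)
  scafs <- setdiff(unique(genes_tbl$scaffold), cfg$chromosomes)
  if (length(scafs)) {
    slen <- vapply(scafs, function(s)
      max(genes_tbl$end[genes_tbl$scaffold == s]) + 1000, numeric(1))
    seqlens <- c(seqlens, slen)
  }
  sim <- structure(list(
    annotation = new_annotation(genes_tbl, seqlens),
    proteins = unlist(proteins),
    cds = unlist(cds),
    hits = if (length(hits)) validate_domain_hits(bind_rows(hits)) else
      tibble(gene_id = character(), domain = character(),
             aa_start = integer(), aa_end = integer(), score = numeric()),
    truth = list(genes = bind_rows(truth),
                 links = bind_rows(wgd_links, self_links))
  ), class = "synth_genome")
  if (!is.null(out_dir)) sim$files <- write_genome(sim, out_dir)
  sim
}

#' Write a synthetic genome to disk
#'
#' Emits `genes.gff3`, `proteins.faa`, `cds.fna`, `hits.tsv` and the
#' ground-truth tables `truth_genes.tsv` / `truth_links.tsv`. All files
#' are plain text and parse back through the package readers.
#'
#' @param sim a `synth_genome` from [generate_genome()].
#' @param dir output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_genome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gff = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.faa"),
    cds = file.path(dir, "cds.fna"),
    hits = file.path(dir, "hits.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_links = file.path(dir, "truth_links.tsv")
  )
  write_gff3(sim$annotation, paths[["gff"]])
  write_fasta(sim$proteins, paths[["proteins"]])
  write_fasta(sim$cds, paths[["cds"]])
  write_domain_hits(sim$hits, paths[["hits"]])
  readr::write_tsv(sim$truth$genes, paths[["truth_genes"]], progress = FALSE)
  readr::write_tsv(sim$truth$links, paths[["truth_links"]], progress = FALSE)
  invisible(paths)
}
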