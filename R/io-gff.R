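#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features into a genome annotation. External
#' GFF3 coordinates are 1-based inclusive; internally every interval is
#' 0-based half-open, so a gene printed at columns `start=101, end=200`
#' becomes the interval `[100, 200)` of length 100. All downstream modules
#' see only the internal convention.
#'
#' A sequence id matching `^[Cc]hr` is treated as a chromosome (the gene is
#' "anchored"); any other id is an unplaced scaffold and the `chromosome`
#' field is `NA`. Chromosome and scaffold lengths are taken from
#' `##sequence-region` pragmas when present.
#'
#' @param path path to a GFF3 file.
#' @return An object of class `rga_annotation`: a list with
#'   * `genes`: tibble with columns `gene_id`, `scaffold`, `chromosome`,
#'     `start`, `end`, `strand`, `n_exons`, sorted by scaffold and start;
#'   * `chromosome_lengths`: named numeric vector (base pairs);
#'   * `genome_mb`: total length of all declared sequences in megabases.
#' @export
read_gff3 <- function(path) {
  assert_that(file.exists(path), paste0("GFF3 file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfields <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfields != 9)) {
    bad <- body[which(nfields != 9)[1]]
    abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                  bad, nfields[which(nfields != 9)[1]]))
  }
  seqlens <- parse_sequence_regions(lines)

  gff <- suppressWarnings(as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")
  )))
  gff$Parent <- vapply(gff$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                       character(1))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  assert_that(nrow(genes) > 0, "GFF3 contains no gene features")
  assert_that(!anyNA(genes$ID), "gene feature without an ID attribute")

  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  tx2gene <- setNames(mrna$Parent, mrna$ID)
  exons <- gff[gff$type == "exon", , drop = FALSE]
  exon_gene <- ifelse(exons$Parent %in% names(tx2gene),
                      tx2gene[exons$Parent], exons$Parent)
  exon_counts <- table(exon_gene)

  tbl <- tibble(
    gene_id = as.character(genes$ID),
    scaffold = as.character(genes$seqid),
    chromosome = ifelse(grepl("^[Cc]hr", as.character(genes$seqid)),
                        as.character(genes$seqid), NA_character_),
    start = as.numeric(genes$start) - 1,  # to 0-based half-open
    end = as.numeric(genes$end),
    strand = ifelse(as.character(genes$strand) %in% c("+", "-"),
                    as.character(genes$strand), "+"),
    n_exons = as.integer(ifelse(is.na(exon_counts[genes$ID]), 1L,
                                exon_counts[genes$ID]))
  ) |>
    arrange(.data$scaffold, .data$start)
  assert_that(all(tbl$start < tbl$end), "gene with start >= end")

  new_annotation(tbl, seqlens)
}

new_annotation <- function(genes, chromosome_lengths = numeric()) {
  named <- unique(stats::na.omit(genes$chromosome))
  missing <- setdiff(named, names(chromosome_lengths))
  if (length(missing)) {
    # fall back to the rightmost gene end when no pragma declared the length
    ends <- vapply(missing, function(ch) max(genes$end[genes$chromosome %in% ch]),
                   numeric(1))
    chromosome_lengths <- c(chromosome_lengths, setNames(ends, missing))
  }
  structure(
    list(genes = genes,
         chromosome_lengths = chromosome_lengths,
         genome_mb = sum(chromosome_lengths) / 1e6),
    class = "rga_annotation"
  )
}

parse_sequence_regions <- function(lines) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) return(numeric())
  parts <- strsplit(trimws(sr), "\\s+")
  setNames(vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
           vapply(parts, function(p) p[2], character(1)))
}

#' Write a genome annotation to GFF3
#'
#' Emits `##sequence-region` pragmas and one gene/mRNA pair per gene with
#' `n_exons` exon features partitioning the gene span. Internal 0-based
#' half-open coordinates are converted back to 1-based inclusive columns, so
#' `read_gff3(write_gff3(x))` is the identity on
#' (gene_id, scaffold, start, end, strand, n_exons).
#'
#' @param annotation an `rga_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  out <- c("##gff-version 3")
  cl <- annotation$chromosome_lengths
  seqs <- unique(genes$scaffold)
  for (s in seqs) {
    len <- if (s %in% names(cl)) cl[[s]] else max(genes$end[genes$scaffold == s])
    out <- c(out, sprintf("##sequence-region %s 1 %d", s, as.integer(len)))
  }
  fmt <- function(seqid, type, start0, end0, strand, attrs) {
    sprintf("%s\trgatools\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, as.integer(start0) + 1L, as.integer(end0), strand, attrs)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    out <- c(out,
             fmt(g$scaffold, "gene", g$start, g$end, g$strand,
                 paste0("ID=", g$gene_id)),
             fmt(g$scaffold, "mRNA", g$start, g$end, g$strand,
                 paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id)))
    bounds <- round(seq(g$start, g$end, length.out = g$n_exons + 1))
    for (k in seq_len(g$n_exons)) {
      out <- c(out,
               fmt(g$scaffold, "exon", bounds[k], bounds[k + 1], g$strand,
                   sprintf("ID=%s.t1.exon%d;Parent=%s.t1", g$gene_id, k, g$gene_id)))
    }
    out <- c(out,
             fmt(g$scaffold, "CDS", g$start, g$end, g$strand,
                 paste0("ID=", g$gene_id, ".t1.cds;Parent=", g$gene_id, ".t1")))
  }
  writeLines(out, path)
  invisible(path)
}
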