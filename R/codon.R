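BASES <- c("T", "C", "A", "G")

translate_cds <- function(cds) {
  assert_that(nchar(cds) %% 3 == 0, "CDS length must be divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Thread CDS pairs onto a protein alignment
#'
#' Maps each column of a pairwise protein alignment back to the underlying
#' codons ("back-threading"), producing a codon-aware nucleotide alignment
#' in which every protein gap becomes a gap triple. Back-translation of the
#' result reproduces both CDS exactly. A terminal stop codon on either CDS
#' is tolerated and dropped.
#'
#' @param aln_a,aln_b gapped protein strings of equal length (one aligned
#'   pair).
#' @param cds_a,cds_b ungapped coding sequences; each must translate
#'   (standard code) to the ungapped protein of its alignment row.
#' @return List with codon-aligned strings `a` and `b` (lengths divisible
#'   by 3).
#' @export
codon_align <- function(aln_a, aln_b, cds_a, cds_b) {
  assert_that(nchar(aln_a) == nchar(aln_b),
              "aligned protein rows must have equal length")
  thread_one <- function(aln, cds, who) {
    cds <- toupper(cds)
    assert_that(nchar(cds) %% 3 == 0,
                paste0("CDS of ", who, " is not divisible by 3"))
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    gc <- Biostrings::GENETIC_CODE
    aa <- unname(gc[codons])
    # tolerate one terminal stop codon
    if (length(aa) > 1 && !is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
      codons <- codons[-length(codons)]
    }
    stops <- which(aa == "*")
    if (length(stops)) {
      abort(sprintf("internal stop codon in %s at codon %d", who, stops[1]))
    }
    cols <- strsplit(toupper(aln), "")[[1]]
    residues <- cols[cols != "-"]
    assert_that(length(residues) == length(codons),
                paste0("protein/CDS length mismatch for ", who))
    mism <- which(residues != aa & aa != "X" & residues != "X")
    if (length(mism)) {
      abort(sprintf("translation mismatch for %s at residue %d: %s vs %s",
                    who, mism[1], residues[mism[1]], aa[mism[1]]))
    }
    out <- character(length(cols))
    out[cols == "-"] <- "---"
    out[cols != "-"] <- codons
    paste(out, collapse = "")
  }
  list(a = thread_one(aln_a, cds_a, "sequence a"),
       b = thread_one(aln_b, cds_b, "sequence b"))
}

# ---- NG86 lookup tables (memoized) ----------------------------------------

# Per-codon synonymous-site count: at each position the fraction of the
# three possible changes that are synonymous (changes to stop codons count
# as nonsynonymous so that S + N = 3 per codon).
ng86_site_table <- function() {
  if (!is.null(.rga_cache$ng86_sites)) return(.rga_cache$ng86_sites)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  syn <- setNames(numeric(length(sense)), sense)
  for (codon in sense) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- b
        if (gc[[alt]] != "*" && gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
      }
    }
    syn[codon] <- s
  }
  .rga_cache$ng86_sites <- syn
  syn
}

# Pairwise synonymous/nonsynonymous difference counts between sense
# codons, averaged over all shortest mutational pathways that avoid stop
# codons (all pathways if every one is blocked).
ng86_diff_tables <- function() {
  if (!is.null(.rga_cache$ng86_diffs)) return(.rga_cache$ng86_diffs)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  k <- length(sense)
  sd_m <- matrix(0, k, k, dimnames = list(sense, sense))
  nd_m <- matrix(0, k, k, dimnames = list(sense, sense))
  step_counts <- function(from, to) {
    # one-substitution step: synonymous or not
    if (gc[[from]] == gc[[to]]) c(1, 0) else c(0, 1)
  }
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- sense[i]; b <- sense[j]
      diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      nd <- length(diff_pos)
      if (nd == 0) next
      perms <- combinat_perms(diff_pos)
      totals <- list()
      for (path in perms) {
        cur <- a
        sdc <- 0; ndc <- 0; blocked <- FALSE
        for (pos in path) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(b, pos, pos)
          if (gc[[nxt]] == "*") { blocked <- TRUE; break }
          st <- step_counts(cur, nxt)
          sdc <- sdc + st[1]; ndc <- ndc + st[2]
          cur <- nxt
        }
        totals[[length(totals) + 1]] <-
          c(sd = sdc, nd = ndc, blocked = as.numeric(blocked))
      }
      tot <- do.call(rbind, totals)
      open <- tot[tot[, "blocked"] == 0, , drop = FALSE]
      use <- if (nrow(open) > 0) open else {
        # no stop-free pathway: average over all, scoring the blocked step
        # and the remainder through the stop codon as nonsynonymous
        full <- t(apply(tot, 1, function(r) {
          c(sd = r[["sd"]], nd = nd - r[["sd"]])
        }))
        full
      }
      sd_m[i, j] <- sd_m[j, i] <- mean(use[, "sd"])
      nd_m[i, j] <- nd_m[j, i] <- mean(use[, "nd"])
    }
  }
  .rga_cache$ng86_diffs <- list(sd = sd_m, nd = nd_m)
  .rga_cache$ng86_diffs
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Counts synonymous (S) and nonsynonymous (N) sites as per-codon fractions
#' averaged over the two sequences, and synonymous (Sd) and nonsynonymous
#' (Nd) differences averaged over all shortest mutational pathways avoiding
#' stop codons. Proportions are corrected for multiple hits with the
#' Jukes-Cantor formula \eqn{d = -3/4 \ln(1 - 4p/3)}, defined for
#' `p < 0.75`; beyond that the estimate is flagged saturated.
#'
#' Codon columns containing a gap, an ambiguous base, or a stop codon in
#' either sequence are skipped pairwise.
#'
#' @param codon_a,codon_b aligned codon strings (equal lengths divisible by
#'   3), e.g. from [codon_align()].
#' @return One-row tibble with `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `ks`,
#'   `ka`, `n_codons` (compared codons) and `flags`.
#' @export
ng86 <- function(codon_a, codon_b) {
  as_tibble(ng86_core(codon_a, codon_b))
}

# list-returning workhorse behind ng86(); kept cheap because all-pairs Ks
# calls it hundreds of thousands of times
ng86_core <- function(codon_a, codon_b) {
  assert_that(nchar(codon_a) == nchar(codon_b),
              "codon alignment rows must have equal length")
  assert_that(nchar(codon_a) %% 3 == 0, "codon alignment length not divisible by 3")
  sites <- ng86_site_table()
  diffs <- ng86_diff_tables()
  ca <- substring(codon_a, seq(1, nchar(codon_a), 3), seq(3, nchar(codon_a), 3))
  cb <- substring(codon_b, seq(1, nchar(codon_b), 3), seq(3, nchar(codon_b), 3))
  usable <- ca %in% names(sites) & cb %in% names(sites)
  ca <- ca[usable]; cb <- cb[usable]
  n_codons <- length(ca)
  if (n_codons == 0) {
    return(list(S = 0, N = 0, Sd = 0, Nd = 0, ps = NA_real_, pn = NA_real_,
                ks = NA_real_, ka = NA_real_, n_codons = 0L,
                flags = "zero_sites"))
  }
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * n_codons - S
  Sd <- sum(diffs$sd[cbind(ca, cb)])
  Nd <- sum(diffs$nd[cbind(ca, cb)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  flags <- character()
  if (S <= 0) flags <- c(flags, "zero_sites")
  if (!is.na(ps) && ps >= 0.75) flags <- c(flags, "saturated")
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       ks = jc(ps), ka = jc(pn), n_codons = n_codons,
       flags = flag_string(flags))
}
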