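---
title: "Methods behind rgatools: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind rgatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rgatools` analyses resistance gene analogues (RGAs) — plant genes whose
protein carries the NB-ARC nucleotide-binding domain — from gene models,
sequences and precomputed domain hits, through architecture
classification, allele collapsing, cluster calling, phylogenetics, and
synonymous-divergence (Ks) based duplication analysis. This vignette
records the models and the reasoning behind every tunable parameter and
numerically consequential choice. It states no empirical result beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## Coordinates and inputs

Internally every interval is 0-based half-open; GFF3 input and output are
converted at the boundary (a gene printed at columns 101–200 is the
interval [100, 200), length 100). Only the I/O layer performs that
arithmetic. A sequence id matching `^[Cc]hr` marks a gene as anchored to a
chromosome; anything else is an unplaced scaffold. Domain hits are
consumed from a deliberately minimal 5-column TSV
(`gene_id, domain, aa_start, aa_end, score`) rather than raw HMMER
`--domtblout`, decoupling the pipeline from search-tool versions; the
conversion (target name, domain name, envelope start − 1, envelope end,
domain bit score) is a one-line awk exercise.

## Architecture classification

The class label is read off the left-to-right order of the *first*
occurrences of the TIR, CC, NBS (NB-ARC) and LRR tokens, giving the nine
field-standard labels TNL, NLT, TCNL, TCN, TN, CNL, NL, CN, N. Names such
as NLT and TCNL are positional, so order — not mere presence — must decide
the label. Two conventions complete the grammar:

* a coiled coil detected by scoring (not by an explicit CC hit) inserts
  its C token immediately before N, reflecting the N-terminal role of CC
  regions relative to the switch domain;
* a token order outside the nine names (possible with unusual domain
  arrangements) falls back to the longest class name that is a
  subsequence of the order string, ties resolved towards the N-terminus
  and then alphabetically; N always matches, so every NB-ARC protein gets
  a label.

Proteins with two NB-ARC hits are classified on the first and flagged
`multi_nbs`; kinase and BED hits are carried as flags and never become
class tokens. Genes without an NB-ARC hit are not RGAs and yield no
record.

## Coiled-coil scoring

CC detection is a windowed heptad-propensity scorer in the style of the
classic COILS method. A window of 21 residues (options: 14, 28) slides
over the protein in all seven heptad frames; each window scores the
geometric mean of per-residue, per-heptad-position propensities from the
package's MTK-style table (`coils_propensity_table()`); the best window
score is mapped to a probability through a two-Gaussian likelihood ratio,
`P = G_cc / (G_cc + 30 G_glob)`, with the window-21 calibration
globular ~ N(0.77, 0.20), coiled ~ N(1.63, 0.24) and 30:1 prior odds in
favour of globular. Windows 14 and 28 reuse the same calibration — a
documented approximation, acceptable because the package's default and
tested configuration is window 21. The acceptance threshold is 0.9, a
stringent setting that keeps CC calls specific; the classifier is monotone
in it (raising the threshold can only lose C tokens). A zero-propensity
residue (e.g. proline at a core position) zeroes its window, which is why
proline-rich sequence scores essentially zero.

## Allele collapsing

Heterozygous assemblies predict some genes twice. Two records join when
they lie on the *same scaffold*, their genomic intervals intersect by at
least 1 bp, and their global protein similarity exceeds 0.90 strictly.
Similarity is identities over alignment columns after trimming terminal
gap columns, from a Needleman–Wunsch alignment (BLOSUM62, gap opening 10,
extension 0.5). Protein rather than nucleotide similarity is used because
the comparison is of predicted products, and silent divergence should not
keep two predictions of one gene apart. Components form transitively
(A≈B, B≈C joins A with C even when A–C falls below the threshold, the
behaviour a union of pairwise calls implies); the longest protein — ties
broken by smallest id — represents the component. Alleles are excluded
from clustering, summaries, phylogeny and Ks.

## Cluster calling

A cluster is a maximal chain of ≥ 2 anchored, non-allele RGAs on one
chromosome in which every *adjacent pair* satisfies both conditions: gap
≤ 250,000 bp between the facing interval ends, and ≤ 21 non-RGA ORFs
wholly between the two intervals. The per-adjacent-pair reading of
"within an average of 250 kb" was chosen over a cluster-average-spacing
test because pairwise chaining is order-independent and matches the usual
application of the Arabidopsis-derived rule; the caller's equivalence to a
brute-force enumerator over all contiguous runs is part of the acceptance
suite. The rule is strand-agnostic, and alleles count as RGAs (not as
intervening ORFs). Both thresholds are monotone: relaxing either can only
grow the clustered set.

Summary rounding is fixed for bit-reproducibility: percentages of the
predicted-gene total and per-Mb densities to 2 decimals, mean cluster
sizes to 1 decimal, share percentages to whole percent.

## Distances, neighbor joining, bootstrap, consensus

Pairwise distances from the NBS-domain alignment use the Dayhoff
empirical model by default: each pair's distance is the branch length
maximising the likelihood of its residue-pair counts under
`P(t) = exp(Qt)` (the PROTDIST approach). The Dayhoff exchangeabilities
and frequencies are embedded as constants. Implementation: all pairs are
first evaluated on a shared 160-point log-spaced grid of branch lengths
(one matrix product), then each optimum is polished by scalar optimization
within its bracketing interval; bootstrap replicates skip the polishing,
where grid resolution (a few percent) is ample for topology. Gap handling
is pairwise deletion by default (columns gapped or ambiguous in either
member of a pair are skipped; `complete` deletion is available); a pair
with no comparable columns is an error naming the pair. Saturated pairs
are set to a ceiling (default 10) and flagged. A Kimura-style corrected
distance, `−ln(1 − p − 0.2 p²)`, is available as a fast alternative.

Neighbor joining is the standard Saitou–Nei agglomeration with the
Q-criterion. Determinism is built in rather than achieved by input
jumbling: the matrix is reordered by sorted labels and Q-ties break
towards the lexicographically smallest pair of subtree names (a subtree is
named by its smallest leaf). Negative branch lengths are clamped to zero
with the deficit moved to the sister branch, preserving the pair's summed
length. Trees are unrooted, represented with a trifurcating root.

The bootstrap resamples alignment columns with replacement, fully seeded;
replicates with saturated pairs are retained at the ceiling and tallied.
The consensus is *strict* majority rule: exactly the splits in > 50% of
replicate trees (such splits are pairwise compatible, so the tree always
exists), supports are `100 ×` frequency rounded to integer and attach to
the child node of each split. The greedy extension used by some consensus
tools is deliberately not performed — strictness makes supports exactly
interpretable and the operation testable by hand counting.

Clade utilities take clade definitions as *input* (genome-wide RGA clade
boundaries are analyst-drawn, there is no algorithmic rule to infer) and
report monophyly; genus-specific clades are maximal single-group internal
nodes (parent spans more than one group), a notion invariant to rerooting
along any branch with two multi-group sides.

## Ks and chromosome connections

Codon alignments are obtained by back-threading each CDS pair onto its
global protein alignment — aligning diverged NBS genes at the nucleotide
level breaks reading frames, so a nucleotide-level alignment mode is not
provided. The estimator is Nei–Gojobori (1986): synonymous site counts
are per-codon fractions averaged over the two sequences (a mutation to a
stop codon counts as nonsynonymous, preserving S + N = 3 × codons);
differences in multi-substitution codons are averaged over all shortest
mutational pathways that avoid stop codons (all pathways when every one
is blocked); the proportion `ps = Sd/S` is Jukes–Cantor corrected,
`ks = −3/4 ln(1 − 4 ps/3)`, defined for `ps < 0.75` and flagged saturated
beyond. NG86 was chosen as the transparent, fully specifiable counting
method; the pairwise codon-difference tables are precomputed once per
session.

The pair scope defaults to anchored, non-allele RGAs — for a catalog of
778 anchored representatives this is C(778, 2) = 302,253 pairs. A
chromosome connection is accepted when at least 10 pairs between the two
chromosomes (self-pairs included, capturing intra-chromosome tandem
duplication) have a defined Ks ≤ 0.25; both thresholds are configurable,
the Ks cutoff optionally replaced by the empirical first quartile
(`ks_threshold = NA`). Acceptance is monotone in the Ks threshold and
anti-monotone in the minimum pair count.

## The synthetic genome generator

`generate_genome()` emits a complete data set (GFF3, protein and CDS
FASTA, domain-hit TSV) with ground truth for every planted feature. It
emulates the statistical structure a real RGA catalog exhibits —
clustered placement among background ORFs, tandem families with low
synonymous divergence, WGD chromosome doublets with a controlled Ks mode,
overlapping allele pairs on unplaced scaffolds, chromosome-biased
TIR/non-TIR composition, and coiled-coil heptads in a configurable
fraction of non-TIR RGAs. Key constructions:

* *Domains* are sentinel 12-mers drawn from coil-neutral residues, so the
  hit table can be produced without a profile-HMM search while the NB-ARC
  region still varies between gene families (tag + random filler).
  Planted coiled coils are real heptads (`LEALEGK` × 5) so the scorer is
  genuinely exercised — a planted CNL differs from an NL *only* through
  its heptad segment.
* *WGD partners and tandem members* are synonymous-only mutants: random
  synonymous codon replacements are applied until the NG86 divergence
  from the original reaches the target (doublets default to Ks
  0.12–0.18, tandem members 0.03 from their family base), so the recorded
  "planted Ks" is itself an NG86-true value and partner proteins are
  identical. Allele partners substitute linker residues (never domain
  tags or heptads) to reach the requested similarity, and use coil-free
  architectures so the mutations cannot disturb a planted heptad.
* *Placement* is sequential per chromosome with 300-kb separators between
  planted entities, wider than any plausible `max_gap`, so the planted
  cluster structure is exactly what a correct caller must return.
  Infeasible configurations (more sequence than chromosome) are errors.
* Exon counts are metadata only (TIR-superclass genes draw 4–9, others
  1–6, echoing the higher exon counts of TNL genes); no intron sequence
  is generated. Generation is deterministic from the master seed.

Default scale: 8 chromosomes of 6 Mb, clusters of 2, 4 and 21 members
(the last mirroring the largest cluster reported in apple), four WGD
doublets of 12 pairs, one chromosome ~99% non-TIR, 150 background genes —
about 500 genes and 10,000 anchored RGA pairs, sized so the full pipeline
runs in about a minute on one CPU. What passing tests on these genomes
shows is that each stage recovers what its rule defines on data with
realistic *structure*; they do not show robustness to annotation noise,
fragmented assemblies, pseudogenes, or HMM search errors, none of which
the generator models.

`generate_alignment()` evolves gap-free protein alignments along a random
(or given) tree under the embedded Dayhoff model; random trees draw branch
lengths uniformly from [0.1, 1] × rate — the floor keeps every internal
branch identifiable at moderate alignment lengths, which is what a
topology-recovery check needs.

## Numerical and formatting conventions

* Newick branch lengths print with six decimals; supports are node
  labels; trees round-trip to within 1e-6 per branch.
* FASTA output wraps at 60 columns, making write–read–write
  byte-identical.
* Ties: NJ as above; allele representatives by protein length then id;
  cluster ids by chromosome and span start.
* The pipeline manifest records parameters, seed and MD5 checksums of all
  inputs and outputs and contains no timestamps, so identical runs are
  byte-identical.
* Degenerate inputs: empty catalogs summarise to zeros; `n < 3` taxa,
  overlapping clade definitions, unknown domain labels, unmapped leaves
  and missing CDS are errors naming the offending items.

## Problem sizes used in checks

The test and acceptance workloads are sized for a single CPU: the
published-table fixture reproduces the genome-wide arithmetic exactly and
in under a second; cluster-caller equivalence runs 200 random layouts of
up to 30 genes over a 3 × 3 parameter grid; NJ exactness uses 100 random
additive 8-leaf matrices; NG86 recovery uses 100 forward-simulated
300-codon pairs at true Ks 0.05/0.1/0.2 (mean within 10%); the end-to-end
genome uses the default generator scale above. These sizes are the
package's choice of a thorough-but-quick regression surface.

## Known limitations

* The coiled-coil propensity table and Gaussian calibration are shipped
  constants in the style of the original MTK table, not a retrained
  model; borderline CC calls near the 0.9 threshold should be treated as
  such.
* NG86 underestimates at high divergence (correction undefined at
  ps ≥ 0.75); no maximum-likelihood codon model is provided, and no
  Ka/Ks selection tests.
* NJ is the only tree method; no least-squares, ML or Bayesian inference.
* The naive equal-length NBS extraction only substitutes for a real
  multiple alignment when domain regions are length-homogeneous (as
  synthetic data guarantees); real data should supply an aligned FASTA.
* Clade boundaries are consumed, never inferred.
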