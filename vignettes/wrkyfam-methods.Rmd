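---
title: "Methods: WRKY family identification, classification and regulation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WRKY family identification, classification and regulation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyfam)
```

## Scope and model

`wrkyfam` implements a desk-scale pipeline for characterizing a plant WRKY
transcription-factor family, organized around the sandalwood (*Santalum
album*) SaWRKY family. The pipeline has five analytic stages — domain
identification, phylogenetic classification, promoter W-box target
prediction with pathway enrichment, tissue expression normalization, and
hormone regulation calling from RT-qPCR — plus seeded synthetic-data
generators that plant known truths for every stage, so the whole pipeline
is testable without access to the *S. album* genome assembly.

## The domain grammar

A WRKY domain is modelled as a conserved heptapeptide followed by a
zinc-finger-like motif:

* **Heptapeptide**: `WRKYGQK` plus the two variants observed in the
  family, `WRKYGKK` and `WRKYGHK` (equivalently `W-R-K-Y-G-[QKH]-K`). The
  consensus set is configurable; these three are the defaults because they
  are the forms that occur in the SaWRKY family table.
* **Zinc finger**: `C-Xa-C-Xb-H-X-Z` downstream of the heptapeptide, with
  `a` in 3–7 and `b` in 22–23 by default (the spacings observed across the
  family), and `Z` the fourth metal-coordinating residue: `H` gives the
  canonical C-C-H-H type, `C` the group III C-C-H-C type, anything else a
  rare variant (C-C-H-T, C-C-H-Y, ...).

The finger search is confined to a 100-residue window after each
heptapeptide and takes the first (leftmost) valid arrangement, preferring
the smallest `a`, then the smallest `b`. No search rule is canonical in
the literature; leftmost-first is deterministic and matches the canonical
domain architecture. Some annotated family members carry *more* finger
labels than heptapeptides (e.g. three labels behind one domain);
`scan_zinc_fingers()` therefore continues scanning for chained
arrangements after the first, each within a window of the previous one and
never across the next heptapeptide. `extract_zinc_finger()` exposes the
plain first-arrangement contract.

**Zinc typing.** A protein with at least one `z = H` finger is typed
C-C-H-H; otherwise the most C-terminal finger's residue decides
(C-C-H-C for group III, or the variant letter). With this rule the
packaged 64-gene family table partitions into 56 C-C-H-H proteins, 5
C-C-H-C proteins and 3 single-variant proteins, matching the published
per-type counts. The alternative rule "type by the last finger always"
would break that partition, which is why the any-H precedence was chosen.

## Group and subgroup classification

Rule-based assignment (`assign_group()`): two or more domains → group I;
one domain with C-C-H-H → group II; one domain with C-C-H-C → group III;
variant or undetected fingers → unresolved, deferred to phylogeny. The
published family contains two single-domain group I members placed by tree
position; the pipeline reproduces that *mechanism* (phylogenetic override)
rather than those specific calls.

Phylogenetic placement (`assign_subgroup()`) aligns domain sequences with
a center-star multiple alignment (the center minimizes summed pairwise
distances, 1 − identity; gaps merge under "once a gap, always a gap"),
computes Poisson-corrected distances (`d = −ln(1 − p)`) after complete
deletion of gapped columns, and builds a neighbor-joining tree. The
distance model deserves a note: the published analysis names a
nucleotide substitution model ("maximum composite likelihood") that cannot
apply to a protein alignment, so the package defaults to the closest
standard protein analogue (Poisson correction) with p-distance as an
option; among-site rate heterogeneity is not modelled because its
parameters would be underdetermined here.

The NJ implementation is Saitou–Nei with two determinism guarantees: ties
on the Q criterion break lexicographically by the smallest leaf label in
each cluster, and negative branch-length estimates are clamped to zero
with the deficit moved to the sibling edge (preserving the joined pair's
path length). On additive matrices NJ is exact, which the tests verify
against random trees up to eight taxa. Bootstrap support resamples
alignment columns with replacement and reports the percentage of replicate
trees containing each full-data bipartition.

Subgroup labels come from labeled reference sequences in the tree. The
tree is midpoint-rooted (a convention is needed to walk "outward" from a
leaf on an unrooted tree) and the first enclosing clade whose references
are unanimous gives the label; failing that, the patristically nearest
reference does. The package does not ship a curated Arabidopsis reference
panel; `gen_subgroup_references()` generates a clearly-synthetic labeled
panel (per-subgroup ancestors with strong between- and mild within-
subgroup divergence) that the placement tests use, and real analyses
should substitute a curated panel. On planted-subgroup simulations,
placement recovers at least 95% of query labels.

## Promoters, W-boxes and enrichment

The promoter is the 2,000 bp immediately upstream of the ATG translation
start (not the transcription start): on the + strand positions
`[cds_start − 2000, cds_start − 1]`, on the − strand positions
`[cds_start + 1, cds_start + 2000]` reverse-complemented. Promoters
truncated by a contig edge are scanned over the available span and
flagged; empty promoters exclude the gene from counting.

The W-box consensus is `(C/T)TGAC(C/T)` (IUPAC `YTGACY`). Both strands
are scanned by default — W-boxes are functional on either strand and the
source analysis does not say which convention it used — and overlapping
matches all count; both choices are configurable. A gene with **at least
five** W-boxes (inclusive threshold) is a potential WRKY target. Counts
are binned 0/1/2/3/4/≥5 for the histogram. Enrichment of the target set
uses the hypergeometric upper tail per pathway with Benjamini–Hochberg
correction — the field default for gene-set enrichment; the source names
no test. The published genome-scale numbers (13,306 W-box genes etc.)
require the original assembly and its unpublished re-annotation and are
out of scope; the procedure is validated on planted synthetic genomes
instead.

## Expression

RPKM is `count / (length_bp/1000) / (mapped_total/1e6)`; heat-map values
are `log2(x + 1)`. The RPKM/FPKM naming follows single-end read
semantics; the two phrases in the source describe the same quantity here.

RT-qPCR relative expression uses the 2^−ΔΔCq method: per replicate,
ΔCq = Cq(target) − mean(Cq of the two reference genes) — the arithmetic
mean of reference Cq values is the standard multi-reference combiner
(equivalent to a geometric mean of linear quantities); ΔΔCq compares
treatment timepoint means to the 0 h calibrator. The p-value gating the
fold-change call is a Welch two-sample t-test on replicate ΔCq values
(the source specifies p < 0.05 but no test; Welch on ΔCq is the
conventional choice and is configurable). A timepoint is **up** when the
fold change strictly exceeds 1.5 and p < 0.05, **down** when strictly
below 0.5 with p < 0.05. A gene's per-hormone call aggregates the 3 h and
6 h timepoints as "any significant timepoint, no contradiction";
contradictory timepoints yield `unchanged`. The 42-gene assay universe is
taken as SaWRKY1–SaWRKY42 (every gene in the published direction lists
falls in that range).

## Synthetic data: what it emulates, and what it does not

* `gen_wrky_protein()` / `gen_family_fasta()` plant heptapeptides and
  finger arrangements with exact spacings. Flanks and spacers exclude W,
  C and H, so planted motifs are the *only* matches and recovery is
  exact; each generated protein is verified against its plan before being
  returned. The family FASTA realizes each of the 64 fixture rows at its
  printed ORF length.
* `gen_genome()` plants exact per-gene W-box counts in 2 kb promoters at
  non-overlapping offsets with random strands; background is
  rejection-sampled free of consensus matches on either strand, and the
  assembled promoter is re-scanned to guarantee the planted count.
* `gen_qpcr()` plants fold changes as Cq shifts (−log2 fold) with
  Normal replicate noise (default SD 0.1 cycles) and near-stable
  reference genes (SD 0.05); the study conditions are triplicates at 0,
  3, 6 h with fold 3.0 for up-regulated, 0.3 for down-regulated genes.
* `gen_count_matrix()` draws Poisson counts whose RPKM is unbiased for the
  planted expression.

These generators emulate the *logical* structure of real data — motif
grammar, coordinate conventions, replicate noise — not its biological
texture: no sequence evolution, no compositional bias, no PCR efficiency
drift, no read-level artifacts. Green tests therefore demonstrate the
pipeline's correctness on data satisfying its stated assumptions, not
performance on a real draft genome.

## Numerical and design choices

* Coordinates: GFF3 and the package's genomic interfaces are 1-based
  inclusive; BED output is 0-based half-open; conversions are centralized
  in the I/O layer. Within-protein positions are 1-based.
* Alignment: Needleman–Wunsch with affine gaps (Gotoh), BLOSUM62
  (packaged as plain text), gap open −10 for the first gapped column and
  −1 for each further column; identity = matches / alignment columns.
  Traceback tie-breaks prefer the substitution state, making reported
  alignments deterministic among co-optima.
* Multi-isoform genes: the first mRNA (file order) provides the exon
  structure.
* Redundancy removal is greedy length-descending identity clustering at
  0.95 by default (the source names CD-HIT but no threshold; 0.95 is a
  conservative default and configurable).
* All stochastic components (generators, bootstrap) take explicit integer
  seeds and restore the caller's RNG state.
* Problem sizes in the test-suite simulations (e.g. 80-gene planted
  genomes, 20-query subgroup recovery, 200-replicate bootstraps at 4–6
  taxa, 1000-draw null calibration) were chosen as the smallest sizes at
  which each property is sharply distinguishable from noise.

## Known limitations

* Profile-HMM search, MEME motif discovery, subcellular prediction and
  read mapping are upstream tools, not reimplemented; an annotation run
  starts from a protein FASTA (optionally pre-filtered by an HMMER
  tabular hit list).
* Exact reproduction of the published tree figure is not attempted: the
  reference panel it used is not enumerated in the source.
* One printed inconsistency is preserved rather than resolved: the family
  table lists SaWRKY1 at 333 aa while the cloning section reports 332 aa
  (stop-codon accounting); the fixture stores the table value.
* The Poisson/p-distance models assume uniform rates across sites;
  saturated pairs (p = 1) are an explicit error under the Poisson model.
* The command-line wrapper exposes the data-in/data-out stages
  (identify, summary, tree, promoters, enrich, qpcr, rnaseq, simulate);
  phylogenetic group/subgroup classification is deliberately library-only
  (`assign_group()` / `assign_subgroup()`) because it requires a
  user-supplied labeled reference panel to be meaningful — the packaged
  panel generator is synthetic.
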