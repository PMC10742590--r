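---
title: "Methods: genome-wide analysis of plant UGT gene families with ugtfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide analysis of plant UGT gene families with ugtfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Family-1 UDP-glycosyltransferases (UGTs) transfer sugars from UDP-sugar
donors onto small-molecule acceptors and are among the largest enzyme
families in plant genomes. Their diagnostic signature is the PSPG box, a
conserved 44-residue C-terminal block that binds the UDP sugar. A typical
genome-wide family survey proceeds in fixed stages: find every protein
carrying the motif, filter to a clean non-redundant family, align the
proteins and build a neighbor-joining (NJ) tree with bootstrap supports,
assign phylogenetic group letters by reference to previously classified
UGTs, map intron positions and phases onto the alignment to read off
conserved intron classes, scan promoters for light-, hormone- and
stress-responsive cis-elements, and classify tissue and stress expression,
including qPCR validation by the 2^-ddCt method. `ugtfam` implements that
whole chain as composable, tested functions, plus a synthetic-data
generator that plants a known truth for every stage so each step has an
exact recovery test.

## Family identification

The motif model is a position-specific scoring matrix built from a gapless
44-column block of reference motifs: column weights are
`log2((count(a) + pc * bg(a)) / (n + pc) / bg(a))` with pseudocount
`pc = 1` and a uniform background by default. Scanning slides the matrix
over each protein and keeps the best window (leftmost on ties).

Significance is an empirical shuffle null: the protein's residues are
permuted `n_shuffles` times and the p value is the fraction of shuffled
best-window scores at least as high as the observed one. The default
threshold is `p <= 1e-5`; the Monte-Carlo resolution `1/n_shuffles` is
recorded on every hit (1000 shuffles in pipeline runs, more for
calibration). Because a shuffled best window is often an exact residue
permutation of the observed window, scores tie up to floating-point
summation order; the rank comparison therefore carries a `1e-9` slack so
ties count as ties regardless of summation order.

Candidate filtering retains significant proteins with lengths inside
`[300, 600]` residues (a window bracketing the lengths typical of plant
UGTs, configurable), and collapses exact-duplicate protein sequences to
the representative with the smallest gene id. Every removal is logged with
a machine-readable reason. Per-protein statistics use average residue
masses (MW in kDa includes one water) and an isoelectric point found by
bisecting the Henderson-Hasselbalch net-charge curve (EMBOSS pKa set,
packaged as data) to `|charge| < 1e-4`.

## Coordinate model

GFF3 is 1-based inclusive and stays 1-based throughout the R interface.
Each gene is represented by one transcript — the longest total CDS, ties
to the lexicographically smallest transcript id — because published
surveys analyse one structure per gene without stating their rule; the
choice is recorded in the family table (`n_transcripts` says when it
mattered). The spliced CDS concatenates segments in transcription order
(reverse complement on the minus strand). A CDS whose length is not a
multiple of 3 is flagged pseudo-CDS and excluded from translation-dependent
stages; ambiguous codons translate to `X`; internal stops flag the record
out of the family set. Promoters are the 1500 bp immediately upstream of
the translation start (the first CDS base, not the transcription start),
clipped at contig edges with the obtained length reported.

## Alignment and phylogeny

Pairwise and profile alignment use affine-gap Gotoh dynamic programming
(BLOSUM62, `gap_open = 10`, `gap_extend = 0.5`, a gap of length g costing
`open + (g-1)*extend`). Traceback ties are fixed: match/mismatch over a
gap in the first profile over a gap in the second, so alignments are
reproducible. The progressive aligner builds a guide tree by UPGMA on a
shared 3-mer distance and merges profiles bottom-up, scoring column pairs
by their mean substitution score; degapping any output row reproduces its
input exactly, and that invariant is tested.

Distances are p-distances with pairwise deletion (columns where either row
is gapped are skipped; a pair with no comparable columns is an error).
This mirrors the quick-NJ convention of common tree software; a Poisson
correction would only rescale distances monotonically and is left out.
NJ follows Saitou-Nei with two fixed rules: a Q-matrix tie joins the pair
whose smallest-leaf labels sort first, and negative branch-length
estimates are clamped to zero with the total deficit recorded as a tree
attribute. On additive matrices NJ is exact, which the tests assert to
1e-9 against path-sum matrices from random trees.

Bootstrap supports resample alignment columns with replacement (default
1000 replicates, seeded), rebuild the NJ tree, and report for each
internal edge the percentage of replicates containing the same
bipartition. Supports are invariant to alignment row order because all
tie-breaks are label-based.

Group assignment formalizes what surveys do by eye: anchors (reference
proteins with known group letters) are placed in the tree; each non-anchor
leaf takes the group of its nearest anchor by patristic distance provided
the smallest clade (on the midpoint-rooted tree) containing both is
anchor-consistent (all anchors inside share one group). Leaves failing the
proviso form maximal unassigned clades, each getting a fresh letter
continuing alphabetically — the mechanism by which novel groups beyond the
classical A–N set get named. An exact distance tie between groups warns
and takes the alphabetically earlier letter. This is an explicit rule, not
a reconstruction of any published tree's manual grouping.

## Intron classes

For each junction between consecutive CDS segments (in transcription
order), `cum_cds` counts the coding nucleotides upstream; the phase is
`cum_cds mod 3` (0 between codons, 1 after the first base, 2 after the
second) and the anchoring residue is `cum_cds %/% 3 + 1`. Records project
onto the protein alignment at the column of that residue, and
single-linkage clustering with a 3-column tolerance groups homologous
sites into classes labelled I-1 onward, left to right. Clustering is by
position only; a class with mixed phases is reported as such rather than
split, so per-class phase percentages can be read off. Tolerance 3 absorbs
small alignment jitter near indels; 0 gives exact-column classes.
Conservation percentages use intron-bearing genes as the denominator
(a class in 39 of 67 intron-bearing genes is 58%, not 39 over the whole
family), and the denominator is recorded in the output. The gain/loss
table reports, per phylogenetic group, the fraction of the group's genes
(including intron-less ones) carrying each class.

## Promoter elements

The cis-element dictionary is data, not code: a TSV of named IUPAC
patterns with categories light/hormone/stress/other. The package ships a
curated transcription of commonly used PlantCARE consensus patterns for
the elements named in plant UGT surveys; it is deliberately user-editable
and the tests do not depend on it — they use a small synthetic dictionary
with non-palindromic, mutually non-complementary patterns so planted
occurrences are unambiguous. Scanning reports every overlapping occurrence
on both strands (configurable to non-overlapping), with IUPAC codes
matching their base sets. Per-gene category counts are zero-filled over
all scanned genes and binned with configurable edges; the defaults mirror
the count brackets conventionally reported (light 0/1–5/6/7–10/>10,
hormone 0/1–5/6–7/>7, stress 0/1–4/>4). Published bin boundaries are
ambiguous at their edges, so the bins are parameters rather than
hard-coded prose.

## Expression and qPCR

A gene is expressed in a tissue iff its value exceeds `tau` (default 0,
i.e. strictly positive, matching the usual practice of dropping all-zero
rows; configurable because RNA-seq noise floors vary). Tissue-specific
means expressed in exactly one tissue. Treatment response uses
`log2((treated + 1) / (control + 1))` with a pseudocount of 1 (recorded in
output metadata; the bias it introduces vanishes as magnitudes grow and
the tests assert recovery of planted folds within 0.05 at magnitudes
>= 100) and flags `|log2FC| > 1` symmetrically up and down. No additional
significance test is invented; replicate-level tables are exported so any
statistics package can consume them.

2^-ddCt: per gene and condition, dCt is the mean target Ct minus the mean
reference-gene Ct; ddCt subtracts the gene's calibrator dCt, so the
calibrator is exactly 1 by construction. Replicate scatter propagates as
`sqrt(sd_target^2 + sd_ref^2)` into asymmetric error bars
`2^-(ddCt +/- sd)`. The whole quantity is invariant to adding a constant
to every Ct, which is tested.

## The synthetic-data generator

`simulate_ugt_study()` emits a toy genome (FASTA), annotation (GFF3), a
PSPG reference block, anchors, dictionary, expression/treatment/Ct tables,
the generating tree, and a `truth.json` with every planted fact. What it
emulates: a gene family descending from one ancestor along a known tree
(group clades joined by a backbone, with one anchor-free clade planted
mid-backbone so group discovery is exercised), per-branch substitutions
and small indels, a motif held at a configured identity to the consensus,
introns gained on clades at planted sites/phases with canonical GT...AG
boundaries, promoters carrying exactly the planted element occurrences on
an otherwise element-free background, and expression/Ct tables realizing
planted plans exactly (noise knobs default to 0 so recovery is exact;
property tests turn noise on). Decoy genes are rejection-sampled to be
motif-free: below the weakest family motif score by a 10-bit margin and
with a coarse shuffle p >= 0.05, so "no decoy is significant" holds by
construction rather than by luck.

What it does not emulate — and hence what passing tests do not show about
real data: realistic codon usage or rate heterogeneity, alternative
splicing beyond truncated variants, UTRs, transposable elements,
alignment-hostile divergence (indels are kept out of the motif and a
+/-2-residue guard band around intron sites so planted truth stays
unambiguous), compositional biases that inflate motif false positives,
and RNA-seq normalization artefacts. Recovery on this generator
demonstrates correctness of the machinery, not field performance on a real
genome.

Default study conditions: 20 family genes in 4 anchored groups plus one
anchor-free clade, 30 decoys, motif identity 0.8, 4 intron sites with
phases 0/1/1/2, a 460-residue ancestor with the motif at residue 380,
1500 bp promoters over 3 chromosomes. Tests also use a 15-gene variant
for intron recovery and a 12-gene variant for fast end-to-end checks;
bootstrap replicates in tests are 100–300 (the estimator is the same at
any replicate count; the default for real runs stays 1000).

## Determinism

Every stochastic step (shuffle null, bootstrap, simulation) takes a seed
and consumes the R RNG in a fixed order; `withr::with_seed` restores the
caller's RNG state. Rerunning the pipeline with the same config produces a
byte-identical `summary.json`, which is asserted in the tests, and the
count identities (groups sum to family size, phases sum to intron count,
chromosomes sum to family size) are asserted inside `run_pipeline()` on
every run.

## Known limitations

The progressive aligner is a straightforward profile-profile scheme, not a
ClustalW/MAFFT replacement; on deeply diverged families its alignments
(and hence intron-class boundaries) will be rougher than a dedicated
aligner's. NJ is distance-based; no likelihood or Bayesian alternative is
provided. The group-assignment rule is one defensible formalization of a
manual practice. The shipped PlantCARE-style dictionary is a curated
approximation of published consensus patterns, not a database export. The
empirical motif p value is Monte-Carlo bounded below by `1/n_shuffles`;
at the default pipeline setting the smallest distinguishable p is 1e-3,
and the 1e-5 operating point is reached when no shuffle matches the
observed score.

## A worked run

```{r}
library(ugtfam)

sim <- simulate_ugt_study(sim_config(seed = 42), dir = "sim")
cfg <- pipeline_config_from_sim(sim, seed = 7)
res <- run_pipeline(cfg, "out")

res$summary$family_size
tidy(res$phylogeny)
autoplot(res$ddct)
```
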