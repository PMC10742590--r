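# ugtfam

Genome-wide identification and evolutionary analysis of plant family-1
UDP-glycosyltransferase (UGT) gene families, as a reusable, tested R
pipeline.

Plant UGTs transfer sugars from UDP-sugar donors onto metabolites and are
diagnosed by the PSPG box, a conserved 44-residue C-terminal motif. Surveys
of the family in a new genome all follow the same chain of analyses, and
`ugtfam` implements each link as a composable function:

- **Identification** — a 44-column position-specific scoring matrix
  (log-odds `log2((c_a + pc·bg_a)/(n + pc)/bg_a)`) scanned over every
  annotated protein, with an empirical shuffle-null p value
  (`p = #{shuffled best scores ≥ observed}/N`, threshold `1e-5`), length
  filtering and duplicate collapse; protein length, MW and pI per member.
- **Phylogeny** — progressive multiple alignment (affine-gap Gotoh,
  BLOSUM62), pairwise-deletion p-distances, Saitou–Nei neighbor joining
  (exact on additive matrices), column-bootstrap supports
  (% of replicate trees containing each bipartition), and group-letter
  assignment from reference anchors with fresh letters for anchor-free
  clades.
- **Intron evolution** — intron phases (`phase = cum_cds mod 3`),
  protein-residue anchors projected onto alignment columns, single-linkage
  positional classes I-1, I-2, …, conservation percentages over
  intron-bearing genes, and a group × class gain/loss table.
- **Promoters** — 1500 bp upstream of the translation start scanned
  against an editable IUPAC cis-element dictionary (light / hormone /
  stress categories), with per-gene counts and binned summaries.
- **Expression & qPCR** — tissue-expression calls and tissue-specific
  tallies, `log2((treated+1)/(control+1))` fold-change flags at
  |log2FC| > 1, and 2^−ΔΔCt relative quantification with replicate error
  propagation.
- **Synthetic data** — `simulate_ugt_study()` plants a complete ground
  truth (family membership, tree and groups, intron sites and phases,
  promoter element counts, expression and ΔΔCt plans) so every stage has
  an exact recovery test without downloading anything.

The methods vignette (`vignettes/ugt-family-analysis.Rmd`) documents the
models, parameter choices and limitations.

## Worked example

Simulate a study (20 family genes in 5 clades plus 30 motif-free decoys on
3 chromosomes) and run the whole pipeline on it:

```r
library(ugtfam)

sim <- simulate_ugt_study(sim_config(seed = 42), dir = "sim")
cfg <- pipeline_config_from_sim(sim, seed = 7)
res <- run_pipeline(cfg, "out")
```

The family table carries per-protein statistics and gene-model context:

```
  gene_id length mw_kda    pi chrom exon_count
1 g001       460   53.1  8.29 chr01          1
2 g002       464   53.8  8.31 chr01          1
3 g003       464   53.9  8.56 chr01          1
```

All 50 annotated genes are scanned; exactly the 20 planted members survive
the p ≤ 1e-5 / length / duplicate filters. Group letters recover the
planted clades, including the fresh letter E for the anchor-free clade:

```
A B C D E
4 4 4 4 4
```

Intron classes recover the four planted homologous sites with their
phases (0, 1, 1, 2); percentages are over the 6 intron-bearing genes:

```
  class_label n_introns n_genes col_min col_max phase0 phase1 phase2 pct_genes
1 I-1                 2       2      62      62      2      0      0      33.3
2 I-2                 4       4     155     155      0      4      0      66.7
3 I-3                 4       4     246     246      0      4      0      66.7
4 I-4                 2       2     336     336      0      0      2      33.3
```

Expression calls find the planted tissue-specific genes (3 leaf, 2 root,
2 stolon, 1 young tuber), the treatment contrast flags 5 up- and
3 down-regulated genes, and the ΔΔCt table reproduces the planted ladder
exactly (calibrator ≡ 1):

```
  gene  condition delta_ct  ddct rel_expr
1 g001  0h               5   0       1
2 g001  6h               4  -1       2
3 g001  12h              3  -2       4
4 g001  24h              2  -3       8
```

`glance()` on the phylogeny summarizes the bootstrap (1000 replicates
here): 20 tips, 17 internal splits, mean support 96.4%, minimum 71.7%.
`tidy()`, `glance()` and `autoplot()` methods are provided for the model,
phylogeny, ΔΔCt and promoter-count objects.

A thin command-line wrapper lives at `inst/cli/ugtfam.R`
(`simulate` and `run` subcommands over the same functions).

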