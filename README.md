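# mhcatlas

Organism-wide analysis of MHC class I immunopeptidome atlases in R.

Mass-spectrometry immunopeptidomics now produces atlas-scale catalogs of
the peptides presented by MHC class I molecules across dozens of tissues
and subjects. `mhcatlas` implements the downstream statistics such an
atlas needs, end to end:

* **Binder filtering and allotype assignment** — keep 8–12-mers with
  binding percentile rank ≤ 2.0 and assign each peptide to its best-rank
  (argmin) allele.
* **Repertoire landscape** — per-tissue distinct peptide counts, tissue
  connectivity matrices (shared peptides off-diagonal, tissue-unique
  counts on the diagonal), tissue-specific vs. core-shared repertoire
  fractions, tissue PCA on log10 intensities, and Spearman trends of
  presentation breadth against abundance and binding affinity.
* **Allotype enrichment** — per-subject allele shares per tissue,
  fold enrichment against the mean share in the other tissues
  (`share_focal / mean(share_other)`), cross-subject averaging and
  flagging at ≥ 1.5-fold.
* **Expression linkage** — gene classes by peptide output, tissue
  z-score matrices `z = (x_t − mean(x)) / sd(x)` of tissue-specific
  source-gene expression, molecular-weight comparisons.
* **Universal peptides and conservation** — housekeeping/universal
  peptide selection (all-tissues rule for a single inbred strain; a
  three-criterion union for heterogeneous human donors), strand-aware
  promoters (2000 bp up / 200 bp down of the TSS), 12-bp sliding-window
  conservation scores (max of window means) and Wilcoxon rank-sum
  comparison of universal vs. tissue-specific source genes.
* **Proteome-wide screen** — per-protein OLS of per-tissue peptide
  counts on log10 protein abundance; hits at R² > 0.4 with p < 0.01
  (mouse) or p < 0.05 in ≥ 2 subjects (human), ≥ 10 tissue pairs;
  permutation calibration of the false-positive rate.
* **Synthetic cohorts** — `generate_cohort()` draws peptide catalogs,
  expression and protein matrices, gene models and conservation tracks
  with planted, machine-readable ground truth, so the whole pipeline is
  testable without any external download.

It reads plain TSV tables (peptides, matrices), BED6/BED12 gene models
and bedGraph conservation tracks, and is aimed at computational
immunologists working with multi-tissue immunopeptidome resources.

## Worked example

```r
library(mhcatlas)
cohort  <- generate_cohort(cohort_config(species = "mouse", seed = 1))
catalog <- filter_binders(cohort$catalog)
catalog
#> peptide_catalog: 1278 observations | 588 distinct peptides | 10 tissues | 1 subject(s) | species: mouse

part <- partition_specificity(catalog)
part$tissue_specific$fraction$label
#> [1] "44%"        # 258 of 588 peptides seen in exactly one tissue

sel <- select_universal(catalog, "mouse")
length(sel$peptides); sel$fraction$label
#> [1] 10
#> [1] "1.7%"       # peptides detected in all 10 tissues

scr <- run_screen(cohort$protein, count_per_tissue(catalog),
                  screen_config("mouse"))
scr$summary$n_hits
#> [1] 26           # includes all 20 planted correlated proteins
```

The tissue-specific fraction says how much of the repertoire is private
to one tissue; the universal fraction is the small core presented
everywhere; the screen hits are proteins whose abundance profile tracks
how many peptides each tissue presents — candidate antigen-processing
components. Here the screen recovers 20/20 planted proteins with a ~1%
false-hit rate among the independent ones.

A full run (filter → landscape → enrichment → linkage → universal →
conservation → screen) from one YAML config:

```r
run_pipeline(list(simulate = TRUE, species = "mouse", seed = 1,
                  outdir = "out"))
```

or from a shell via the thin wrapper `inst/cli/mhcatlas.R`
(`simulate` and `run` subcommands).

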