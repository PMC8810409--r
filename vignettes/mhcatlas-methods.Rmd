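---
title: "Methods: organism-wide immunopeptidome analysis with mhcatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organism-wide immunopeptidome analysis with mhcatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcatlas)
options(mhcatlas.quiet = TRUE)
```

# Scope and model

`mhcatlas` analyses multi-tissue, multi-subject MHC class I immunopeptidome
atlases: tables of eluted peptides with subject, tissue, assigned allotype,
binding percentile rank, and MS intensity, together with gene × tissue
expression (TPM), protein × tissue label-free abundance, gene models and
per-base conservation tracks. The pipeline covers:

1. **Binder filtering** — peptides of length 8–12 with percentile rank
   ≤ 2.0 (both bounds inclusive) are retained as class I binders; the
   best-rank (argmin) allele is the assigned allotype, ties broken
   lexicographically so results are deterministic.
2. **Landscape statistics** — per-tissue distinct peptide counts, tissue
   connectivity matrices (shared counts off the diagonal, tissue-*unique*
   counts on the diagonal), tissue-specific and core-shared repertoire
   fractions, tissue PCA on log10 intensity vectors, and rank correlations
   of presentation breadth against abundance and affinity.
3. **Allotype enrichment** — per-subject shares of each tissue's assigned
   peptides per allele, converted to fold enrichments, averaged across
   subjects and flagged at ≥ 1.5-fold.
4. **Expression linkage** — classification of genes by their peptide
   output, tissue z-score matrices of tissue-specific source-gene
   expression, and a molecular-weight comparison.
5. **Universal peptides and conservation** — housekeeping/universal
   peptide selection (single-strain all-tissues rule, or the three-criterion
   union for heterogeneous human donors), strand-aware promoter extraction,
   12-bp sliding-window conservation scores, and rank-sum comparison of the
   score distributions.
6. **Proteome screen** — per-protein ordinary least squares of per-tissue
   peptide counts on log10 protein abundance with a dual R² / p threshold,
   multi-subject replication, and permutation false-positive calibration.

# Key parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| binder length | 8–12 aa | canonical class I ligand lengths |
| binder rank | ≤ 2.0 | conventional percentile-rank binder definition |
| enrichment flag | mean fold ≥ 1.5 | the threshold used for atlas-wide trend reporting |
| promoter | 2000 bp upstream, 200 bp downstream of the TSS, strand-aware | standard housekeeping-gene promoter window |
| conservation window | 12 bp, step 1, score = max window mean | see below |
| screen | R² > 0.4; p < 0.01 (mouse) or < 0.05 in ≥ 2 subjects (human); ≥ 10 pairs | R² 0.4 keeps the null false-positive rate below ~5% at ten tissues; ten pairs is the minimal defensible size for a simple regression |

## Enrichment: denominator convention

Two conventions exist for the fold-enrichment denominator: the mean share
over *all* tissues (inclusive) or over the *other* tissues (exclusive).
The worked numbers this analysis style reports (a 55% share against a 22%
mean elsewhere giving 2.5-fold) follow the exclusive convention, so that
is the default; inclusive mode is available (`enrichment(mode =
"inclusive")`) and has the algebraic property that each allele's
enrichments average exactly 1 across tissues, which the tests exploit.
The two modes converge as the number of tissues grows.

## Conservation scoring choices

"Maximum conservation in a 12-bp sliding window" is ambiguous between the
maximum single base and the maximum window *mean*; we use the maximum of
window means, since per-base maxima would make the window width
irrelevant. Windows containing missing bases are skipped; a region shorter
than 12 bp is scored as the mean of its available bases, and a region with
no usable window falls back to the same mean; fully missing regions are
dropped and counted. Exons are scored individually so windows never
straddle introns, and the group CDFs are built per region by default
(`unit = "gene"` collapses exon scores to a per-gene maximum) — the unit
feeding published CDFs is not derivable from figure text, so both are
provided.

## Universal selection (human)

Donors with fewer than 14 sampled tissues are excluded to keep the
"all tissues of a donor" criterion meaningful. Criterion c2 ("present in
every sample whose donor carries the assigned allele") additionally
requires the allele to occur in at least 2 samples, otherwise an allele
seen once would trivially qualify its peptides. The top-100 frequency
criterion keeps all peptides tied at the 100th rank and logs the resulting
count.

## Numerical conventions

* Coordinates are 0-based, half-open everywhere internally (BED/bedGraph
  native convention on disk).
* Duplicate (sequence, tissue, subject) observations keep the maximum
  intensity, best rank, and the union of source genes: pulldown depths are
  heterogeneous and not normalized, so a rank-preserving, non-additive
  aggregation is the defensible choice.
* Percent labels round half-up to integer percent, switching to one
  decimal below 2% so small repertoire fractions are not flattened.
* z-scores use the sample (n−1) standard deviation; zero-sd rows are
  returned as zeros and flagged.
* PCA: tissues are observations, peptides variables; undetected peptides
  contribute 0 after log10 of detected intensities; variables are centered
  and unit-scaled by default (`scale_unit = FALSE` switches this off; the
  choice is recorded in the output metadata because it is not derivable
  from published figures).
* The regression screen drops missing and non-positive abundances
  pairwise before log10, computes the two-sided t-test on the slope
  (equivalent to the F-test in a simple regression), applies no
  multiple-testing correction (matching the raw-threshold design of this
  analysis style), and merges jejunum + duodenum into a small-intestine
  average by a configurable map.

# The synthetic cohort generator

Real atlases cannot be bundled, so `generate_cohort()` draws desk-scale
cohorts with known structure:

* **Genes** fall into universal-source (high TPM everywhere),
  tissue-restricted (high TPM in one home tissue; their planted peptide is
  detected only there) and background classes. Defaults are 10/30/600
  genes with ~4 peptides each over 10 tissues — chosen so that tissues
  carry a few hundred assigned peptides each, the sparse-but-not-thin
  regime in which real per-tissue immunopeptidomes live.
* **Detection** is logistic: log-odds = −3 + 1.2·log10(TPM+1) − 0.5·rank.
  This couples detectability to transcription (driving the gene-class and
  breadth trends) and to binding rank. Planted universal peptides are
  forced detected in every tissue; planted tissue-specific peptides only
  at home.
* **Allotype enrichment** is planted by multiplying the detection odds of
  one allele's peptides in one tissue by a fold (default 3) in every
  subject carrying the allele. Because detection saturates, the realized
  share enrichment is below the odds fold (typically 1.6–2.1 under
  defaults), comfortably above the 1.5 flagging threshold.
* **Conservation** is drawn per base from class-specific Beta
  distributions — Beta(8,2) for universal-source, Beta(2,8) for
  tissue-restricted, Beta(2,5) for background — on a single
  pseudo-chromosome with genes laid end-to-end (3 × 100 bp exons, 80 bp
  introns, 2200 bp margins); intergenic bases are missing, which also
  exercises the missing-data rules.
* **Correlated proteins** (default 20 background proteins) have log10
  abundance linear in the per-tissue peptide count with effect 0.5 log10
  units per count SD and noise SD 0.15; all other proteins are
  independent of the counts. `generate_null_screen()` draws a fully
  independent abundance/count pair for calibration.
* Rank scores are uniform on (0, 5] for ordinary peptides and (0, 2] for
  planted ones, and lengths span 7–13 for ordinary peptides, so the binder
  filter is genuinely exercised.

A fixed seed reproduces every output byte-identically; all randomness in
a pipeline run flows from the single `seed` entry of the run config.

What the generator does **not** emulate: peptide sequence biology
(cleavage and anchor motifs), shared peptides across alleles, batch and
pulldown-depth artifacts, isoform structure, or realistic tissue
correlation structure in expression. Passing tests therefore demonstrate
that the statistical machinery recovers planted structure under the
stated model — not that the biological conclusions of any particular
atlas are reproduced.

# Problem sizes used in the shipped tests

The test suite and acceptance checks run cohorts of roughly 640–700 genes
× 10 tissues (≤ 3 subjects), 2000-protein null screens at 10 tissues, and
200-gene-per-class conservation cohorts. These sizes were chosen so each
planted effect is recovered with a comfortable statistical margin while a
full run stays fast on a laptop.

# Known limitations

* The per-protein screen treats tissues as independent observations; real
  tissues share subjects and batches, so its p-values are calibrated only
  in the permutation sense.
* Human universal-peptide criterion c2 assigns each peptide its modal
  allele across observations; genuinely multi-allelic peptides are not
  modelled.
* The infinite-enrichment sentinel (allele absent in all other tissues)
  propagates through cross-subject means and is flagged rather than
  smoothed; with thin tissues a pseudo-count approach might be preferable.
* `run_pipeline()` plus the `inst/cli/mhcatlas.R` wrapper (subcommands
  `simulate` and `run`) are the orchestration surface; the per-stage
  subcommands map one-to-one onto exported functions, which are the
  intended programmatic interface.
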