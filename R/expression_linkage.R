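# Linkage of peptides to source-gene expression: gene classing, tissue
# z-score matrices, molecular-weight comparison.

# Distinct tissues per peptide (pooled over subjects).
peptide_breadth <- function(catalog) {
  per_tissue <- unique(catalog$observations[, c("sequence", "tissue")])
  table(per_tissue$sequence)
}

# Gene sets behind all peptides / tissue-specific peptides of a catalog.
source_gene_sets <- function(catalog) {
  obs <- catalog$observations
  breadth <- peptide_breadth(catalog)
  spec_seqs <- names(breadth)[breadth == 1]
  all_genes <- sort(unique(unlist(obs$source_genes)))
  spec_genes <- sort(unique(unlist(
    obs$source_genes[obs$sequence %in% spec_seqs])))
  list(all = all_genes, tissue_specific = spec_genes,
       tissue_specific_peptides = spec_seqs)
}

#' Classify expression-matrix genes by their peptide output
#'
#' Genes are labelled by whether they encode any detected peptide and
#' whether they encode at least one tissue-specific (single-tissue) peptide;
#' the classes overlap (a tissue-specific source gene also presents
#' peptides), and a disjoint `primary_label` is provided for plotting
#' (specific > any > none). Peptides crediting several source genes credit
#' all of them unless `drop_multimappers` is set. Per-class distributions of
#' log10(TPM + 1) of each gene's mean expression across tissues are returned
#' with pairwise Wilcoxon rank-sum comparisons.
#'
#' @param catalog a [peptide_catalog()] (typically binder-filtered)
#' @param expression gene x tissue TPM matrix from [read_matrix()]
#' @param drop_multimappers drop peptides with more than one source gene
#' @return list with `table` (tibble: gene_id, presents_peptides,
#'   presents_tissue_specific, primary_label), `log_expression` (named list
#'   of per-class log10(TPM+1) vectors), `tests` (pairwise Wilcoxon
#'   p-values) and `unmapped_fraction` (peptides with no gene in the matrix)
#' @export
classify_genes <- function(catalog, expression, drop_multimappers = FALSE) {
  stopifnot(inherits(catalog, "peptide_catalog"), is.matrix(expression))
  cat2 <- catalog
  if (drop_multimappers) {
    keep <- lengths(cat2$observations$source_genes) <= 1
    cat2$observations <- cat2$observations[keep, , drop = FALSE]
  }
  sets <- source_gene_sets(cat2)
  universe <- rownames(expression)
  if (length(intersect(sets$all, universe)) == 0) {
    stop("no source gene overlaps the expression matrix", call. = FALSE)
  }
  obs <- cat2$observations
  mapped <- vapply(obs$source_genes,
                   function(g) any(g %in% universe), logical(1))
  by_pep <- tapply(mapped, obs$sequence, any)
  unmapped_fraction <- 1 - mean(by_pep)

  tab <- tibble::tibble(
    gene_id = universe,
    presents_peptides = universe %in% sets$all,
    presents_tissue_specific = universe %in% sets$tissue_specific)
  tab$primary_label <- ifelse(tab$presents_tissue_specific, "tissue_specific",
                       ifelse(tab$presents_peptides, "presents_peptides",
                              "presents_none"))
  mean_expr <- rowMeans(expression, na.rm = TRUE)
  logx <- log10(mean_expr + 1)
  classes <- list(
    presents_peptides = logx[tab$presents_peptides],
    tissue_specific = logx[tab$presents_tissue_specific],
    presents_none = logx[!tab$presents_peptides])
  wtest <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  tests <- list(
    any_vs_none = wtest(classes$presents_peptides, classes$presents_none),
    specific_vs_none = wtest(classes$tissue_specific, classes$presents_none),
    specific_vs_any = wtest(classes$tissue_specific,
                            logx[tab$presents_peptides &
                                 !tab$presents_tissue_specific]))
  list(table = tab, log_expression = classes, tests = tests,
       unmapped_fraction = unmapped_fraction)
}

#' Tissue z-score matrix of tissue-specific source-gene expression
#'
#' Genes encoding tissue-specific peptides are grouped by the source tissue
#' (the tissue where their peptide was observed). For each source-tissue
#' group, expression is averaged over the group's genes per tissue, then
#' standardized across tissues: z = (x - mean(x)) / sd(x) with the sample
#' (n - 1) standard deviation. A zero-sd row is set to all zeros and
#' flagged.
#'
#' @param catalog a [peptide_catalog()]
#' @param expression gene x tissue TPM matrix
#' @return matrix (source tissue x tissue) with attributes
#'   `flag_zero_sd` (logical per row) and `n_genes` (genes per row);
#'   source tissues without mapped tissue-specific genes are omitted with a
#'   warning
#' @export
zscore_matrix <- function(catalog, expression) {
  stopifnot(inherits(catalog, "peptide_catalog"), is.matrix(expression))
  if (ncol(expression) < 2) {
    stop("z-scores require expression over at least 2 tissues", call. = FALSE)
  }
  obs <- catalog$observations
  breadth <- peptide_breadth(catalog)
  spec_seqs <- names(breadth)[breadth == 1]
  spec_obs <- obs[obs$sequence %in% spec_seqs, , drop = FALSE]
  genes_by_tissue <- lapply(
    split(spec_obs$source_genes, spec_obs$tissue),
    function(gl) intersect(unique(unlist(gl)), rownames(expression)))
  empty <- names(genes_by_tissue)[lengths(genes_by_tissue) == 0]
  if (length(empty) > 0) {
    warning("source tissue(s) without mapped tissue-specific genes omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
    genes_by_tissue <- genes_by_tissue[lengths(genes_by_tissue) > 0]
  }
  if (length(genes_by_tissue) == 0) {
    stop("no source tissue has mapped tissue-specific genes", call. = FALSE)
  }
  rows <- t(vapply(genes_by_tissue, function(g) {
    colMeans(expression[g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(expression))))
  sds <- apply(rows, 1, stats::sd)
  z <- (rows - rowMeans(rows)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  attr(z, "flag_zero_sd") <- stats::setNames(sds == 0, rownames(z))
  attr(z, "n_genes") <- lengths(genes_by_tissue)
  z
}

#' Molecular-weight comparison of universal versus other source genes
#'
#' Two-sided Wilcoxon rank-sum comparison of protein molecular weights
#' between source genes of universal peptides and other source genes, to
#' ask whether universally presented peptides preferentially originate from
#' heavy proteins.
#'
#' @param universal_genes,other_source_genes character vectors of gene ids
#' @param molecular_weights named numeric vector of molecular weights (Da)
#' @return list with group `medians`, Wilcoxon `statistic`, two-sided
#'   `p_value`, group sizes `n`, and `n_dropped` (genes without a weight)
#' @export
mw_comparison <- function(universal_genes, other_source_genes,
                          molecular_weights) {
  get_mw <- function(genes) {
    mw <- molecular_weights[genes]
    mw[!is.na(mw)]
  }
  a <- get_mw(universal_genes)
  b <- get_mw(other_source_genes)
  n_dropped <- (length(universal_genes) - length(a)) +
    (length(other_source_genes) - length(b))
  if (n_dropped > 0) {
    atlas_log(n_dropped, " gene(s) dropped for missing molecular weight")
  }
  if (length(a) < 3 || length(b) < 3) {
    stop("molecular-weight comparison requires at least 3 weighted genes per group",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(medians = c(universal = stats::median(a), other = stats::median(b)),
       statistic = unname(ht$statistic), p_value = ht$p.value,
       n = c(universal = length(a), other = length(b)),
       n_dropped = n_dropped)
}
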