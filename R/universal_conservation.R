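# Housekeeping/universal peptide selection (mouse and human rules) and
# promoter/exon conservation scoring with cumulative-frequency comparison.

#' Select housekeeping/universal peptides
#'
#' Mouse mode (single inbred strain, one allele set): a peptide is universal
#' when detected in every tissue of the catalog vocabulary. Human mode
#' (heterogeneous donors and HLA types): donors with fewer than
#' `min_tissues_per_donor` sampled tissues are set aside, and a peptide is
#' universal when it satisfies at least one of
#' \itemize{
#'   \item c1: detected in all sampled tissues of at least two donors;
#'   \item c2: detected in every (donor, tissue) sample from donors carrying
#'     the peptide's assigned allele, provided the allele occurs in at least
#'     `min_allele_samples` samples;
#'   \item c3: among the `top_k` peptides observed in the most (donor,
#'     tissue) samples, ties at the k-th rank all included.
#' }
#'
#' @param catalog a [peptide_catalog()]
#' @param species_mode `"mouse"` or `"human"`
#' @param min_tissues_per_donor human mode: minimum distinct tissues sampled
#'   for a donor to enter the selection (guards against donors with few
#'   tissues trivially satisfying "all tissues")
#' @param top_k human mode: size of the frequency criterion c3
#' @param min_allele_samples human mode: minimum samples carrying the
#'   assigned allele for c2 to apply
#' @return list with `peptides` (selected sequences), `criteria` (tibble of
#'   per-peptide criterion indicators), `source_genes`, `fraction`
#'   (a [report_fraction()] over all distinct catalog peptides) and
#'   `n_c3_selected` (size of c3 after ties)
#' @export
select_universal <- function(catalog, species_mode = c("mouse", "human"),
                             min_tissues_per_donor = 14L, top_k = 100L,
                             min_allele_samples = 2L) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  species_mode <- match.arg(species_mode)
  obs <- catalog$observations
  total <- length(unique(obs$sequence))

  if (species_mode == "mouse") {
    if (length(catalog$subjects) > 1) {
      stop("mouse mode expects a single pooled subject; found ",
           length(catalog$subjects),
           " subjects (use species_mode = 'human')", call. = FALSE)
    }
    per_pep <- tapply(obs$tissue, obs$sequence,
                      function(tt) length(unique(tt)))
    sel <- names(per_pep)[per_pep == length(catalog$tissues)]
    criteria <- tibble::tibble(sequence = sel, all_tissues = TRUE)
  } else {
    donor_tissues <- tapply(obs$tissue, obs$subject_id,
                            function(tt) unique(tt))
    eligible <- names(donor_tissues)[lengths(donor_tissues) >=
                                       min_tissues_per_donor]
    if (length(eligible) == 0) {
      stop("no donor reaches ", min_tissues_per_donor, " sampled tissues",
           call. = FALSE)
    }
    eobs <- obs[obs$subject_id %in% eligible, , drop = FALSE]
    # c1: all sampled tissues of >= 2 eligible donors
    pep_donor <- unique(eobs[, c("sequence", "subject_id", "tissue")])
    complete <- dplyr::summarise(
      dplyr::group_by(pep_donor, .data$sequence, .data$subject_id),
      complete = dplyr::n_distinct(.data$tissue) ==
        length(donor_tissues[[.data$subject_id[1]]]),
      .groups = "drop")
    c1_tab <- dplyr::summarise(
      dplyr::group_by(complete, .data$sequence),
      c1 = sum(.data$complete) >= 2, .groups = "drop")
    # samples = (donor, tissue) pairs among eligible donors
    samples <- unique(eobs[, c("subject_id", "tissue")])
    sample_alleles <- lapply(seq_len(nrow(samples)), function(i) {
      catalog$subject_alleles[[samples$subject_id[i]]]
    })
    # c2: present in all samples whose donor carries the assigned allele
    pep_allele <- vapply(split(eobs$allele, eobs$sequence), function(a) {
      a <- a[!is.na(a)]
      if (length(a) == 0) NA_character_ else names(sort(table(a),
                                                        decreasing = TRUE))[1]
    }, character(1))
    pep_samples <- split(paste(eobs$subject_id, eobs$tissue, sep = "\r"),
                         eobs$sequence)
    sample_key <- paste(samples$subject_id, samples$tissue, sep = "\r")
    c2_for <- function(seq) {
      al <- pep_allele[[seq]]
      if (is.na(al)) return(FALSE)
      carrying <- sample_key[vapply(sample_alleles,
                                    function(s) al %in% s, logical(1))]
      length(carrying) >= min_allele_samples &&
        all(carrying %in% pep_samples[[seq]])
    }
    # c3: top-k sample frequency, ties at rank k included
    freq <- vapply(pep_samples, function(s) length(unique(s)), integer(1))
    seqs <- names(freq)
    c3 <- rep(FALSE, length(seqs))
    if (length(seqs) > 0) {
      k <- min(top_k, length(seqs))
      cutoff <- sort(freq, decreasing = TRUE)[k]
      c3 <- freq >= cutoff
      if (sum(c3) > top_k) {
        atlas_log("frequency criterion ties at rank ", top_k, ": ",
                  sum(c3), " peptides selected")
      }
    }
    criteria <- tibble::tibble(
      sequence = seqs,
      c1 = seqs %in% c1_tab$sequence[c1_tab$c1],
      c2 = vapply(seqs, c2_for, logical(1)),
      c3 = c3)
    criteria <- criteria[criteria$c1 | criteria$c2 | criteria$c3, ,
                         drop = FALSE]
    sel <- criteria$sequence
  }

  genes <- sort(unique(unlist(obs$source_genes[obs$sequence %in% sel])))
  frac <- report_fraction(length(sel), max(total, 1L))
  atlas_log("universal peptides: ", length(sel), " of ", total,
            " (", frac$label, ")")
  list(peptides = sel, criteria = criteria, source_genes = genes,
       fraction = frac,
       n_c3_selected = if (species_mode == "human") sum(criteria$c3) else NA_integer_)
}

#' Strand-aware promoter interval of a gene
#'
#' The promoter spans `upstream` bases upstream and `downstream` bases
#' downstream of the transcription start site, in transcription direction:
#' `[tss - upstream, tss + downstream)` on `+` genes and
#' `[tss - downstream, tss + upstream)` on `-` genes, clipped at the
#' chromosome start.
#'
#' @param gene one-row gene model (tibble row or list with `gene_id`,
#'   `chrom`, `strand`, `tss`) or a gene-model tibble (vectorized)
#' @param upstream,downstream extent in bases (defaults 2000 and 200)
#' @return tibble with columns `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open)
#' @export
promoter_region <- function(gene, upstream = 2000L, downstream = 200L) {
  g <- tibble::as_tibble(gene)
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(g)),
            all(g$tss >= 0))
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss - downstream)
  end <- ifelse(plus, g$tss + downstream, g$tss + upstream)
  start <- pmax(start, 0L)
  tibble::tibble(gene_id = g$gene_id, chrom = g$chrom,
                 start = as.integer(start), end = as.integer(end))
}

#' Sliding-window conservation score of a region
#'
#' The score of a region is the maximum over all step-1 windows of
#' `window` bases of the window mean conservation probability. Windows
#' containing missing bases are skipped; a region shorter than the window
#' is scored as the mean of its available bases; a fully missing region
#' scores `NA`.
#'
#' @param track a `conservation_track` from [read_conservation()]
#' @param chrom chromosome
#' @param start,end 0-based half-open interval
#' @param window window width in bases (default 12)
#' @return scalar score in [0, 1], or `NA` if no window (or base) is
#'   available
#' @export
region_conservation <- function(track, chrom, start, end, window = 12L) {
  v <- track_values(track, chrom, start, end)
  if (all(is.na(v))) return(NA_real_)
  if (length(v) < window) return(mean(v, na.rm = TRUE))
  means <- stats::filter(v, rep(1 / window, window), sides = 1)
  means <- means[window:length(v)]  # one mean per complete window; NA if any base missing
  if (all(is.na(means))) return(mean(v, na.rm = TRUE))
  max(means, na.rm = TRUE)
}

#' Score promoter and exon conservation for a set of genes
#'
#' Promoters are derived with [promoter_region()]; exons are scored
#' individually (windows never straddle introns). With `unit = "region"`
#' every region contributes one score; with `unit = "gene"` exon scores are
#' collapsed to their per-gene maximum.
#'
#' @param models gene-model tibble from [read_gene_models()]
#' @param track a `conservation_track`
#' @param upstream,downstream promoter extent (see [promoter_region()])
#' @param window sliding-window width
#' @param unit `"region"` (default) or `"gene"`
#' @return tibble with columns `gene_id`, `feature` (`"promoter"` or
#'   `"exon"`), `score`; regions without any covered base are dropped with
#'   a log entry
#' @export
score_gene_regions <- function(models, track, upstream = 2000L,
                               downstream = 200L, window = 12L,
                               unit = c("region", "gene")) {
  unit <- match.arg(unit)
  prom <- promoter_region(models, upstream = upstream,
                          downstream = downstream)
  clip_end <- function(chrom, end) pmin(end, length(track[[chrom]]))
  rows <- list()
  for (i in seq_len(nrow(models))) {
    chrom <- models$chrom[i]
    pe <- clip_end(chrom, prom$end[i])
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = models$gene_id[i], feature = "promoter",
      score = region_conservation(track, chrom, prom$start[i], pe, window))
    ex <- models$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = models$gene_id[i], feature = "exon",
        score = region_conservation(track, chrom, ex[j, "start"],
                                    clip_end(chrom, ex[j, "end"]), window))
    }
  }
  out <- dplyr::bind_rows(rows)
  n_missing <- sum(is.na(out$score))
  if (n_missing > 0) {
    atlas_log(n_missing, " region(s) without conservation coverage dropped")
    out <- out[!is.na(out$score), , drop = FALSE]
  }
  if (unit == "gene") {
    out <- dplyr::summarise(
      dplyr::group_by(out, .data$gene_id, .data$feature),
      score = max(.data$score), .groups = "drop")
  }
  out
}

#' Compare conservation between universal and tissue-specific source genes
#'
#' Per feature (promoter, exon), compares the score distributions of the
#' two groups with a two-sided Wilcoxon rank-sum test and returns empirical
#' cumulative-frequency curves on [0, 1].
#'
#' @param scores_universal,scores_tissue_specific score tibbles from
#'   [score_gene_regions()]
#' @return named list per feature, each with `p_value`, `median_diff`
#'   (universal minus tissue-specific), `n`, and `cdf` (tibble: score,
#'   cumulative frequency per group)
#' @export
compare_conservation <- function(scores_universal, scores_tissue_specific) {
  feats <- intersect(unique(scores_universal$feature),
                     unique(scores_tissue_specific$feature))
  if (length(feats) == 0) stop("no common feature to compare", call. = FALSE)
  out <- lapply(feats, function(f) {
    a <- scores_universal$score[scores_universal$feature == f]
    b <- scores_tissue_specific$score[scores_tissue_specific$feature == f]
    if (length(a) < 3 || length(b) < 3) {
      stop("conservation comparison requires at least 3 scores per group (",
           f, ")", call. = FALSE)
    }
    ht <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = "two.sided"))
    grid <- sort(unique(c(0, a, b, 1)))
    cdf <- tibble::tibble(
      score = grid,
      universal = stats::ecdf(a)(grid),
      tissue_specific = stats::ecdf(b)(grid))
    list(p_value = ht$p.value,
         median_diff = stats::median(a) - stats::median(b),
         n = c(universal = length(a), tissue_specific = length(b)),
         cdf = cdf)
  })
  stats::setNames(out, feats)
}
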