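# Repertoire landscape: binder filtering, per-tissue counts, connectivity,
# specificity partitioning, tissue PCA, breadth trends, cross-species counts.

#' Filter a catalog to predicted MHC class I binders
#'
#' Retains peptides of length 8-12 with a binding percentile rank at or
#' below 2.0 (the conventional binder definition); both bounds inclusive.
#'
#' @param catalog a [peptide_catalog()]
#' @param min_len,max_len inclusive length bounds (amino acids)
#' @param rank_max inclusive percentile-rank cutoff
#' @return filtered [peptide_catalog()] over the same tissue vocabulary
#' @export
filter_binders <- function(catalog, min_len = 8L, max_len = 12L,
                           rank_max = 2.0) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  obs <- catalog$observations
  if (any(is.na(obs$rank_score))) {
    stop("rank_score must be present on all observations to filter binders",
         call. = FALSE)
  }
  len <- nchar(obs$sequence)
  keep <- len >= min_len & len <= max_len & obs$rank_score <= rank_max
  out <- catalog
  out$observations <- obs[keep, , drop = FALSE]
  out$subjects <- sort(unique(out$observations$subject_id))
  out
}

#' Assign each peptide to its best-binding allele
#'
#' Given percentile ranks of each peptide against each candidate allele, the
#' allele with the lowest (best) rank is assigned. Ties are broken
#' lexicographically by allele name and logged.
#'
#' @param rank_table tibble with columns `sequence`, `allele`, `rank_score`
#' @return tibble with columns `sequence`, `allele`, `rank_score` (one row
#'   per peptide); peptides with no scored allele are absent
#' @export
assign_best_allele <- function(rank_table) {
  rt <- tibble::as_tibble(rank_table)
  stopifnot(all(c("sequence", "allele", "rank_score") %in% names(rt)))
  rt <- rt[!is.na(rt$rank_score), , drop = FALSE]
  rt <- dplyr::arrange(rt, .data$sequence, .data$rank_score, .data$allele)
  ties <- dplyr::summarise(
    dplyr::group_by(rt, .data$sequence),
    tie = sum(.data$rank_score == min(.data$rank_score)) > 1, .groups = "drop")
  if (any(ties$tie)) {
    atlas_log(sum(ties$tie),
              " peptide(s) had tied best ranks; lexicographically first allele assigned")
  }
  dplyr::slice_head(dplyr::group_by(rt, .data$sequence), n = 1) |>
    dplyr::ungroup()
}

#' Count distinct peptides per tissue
#'
#' @param catalog a [peptide_catalog()]
#' @param by_subject if `TRUE`, counts are resolved per subject; otherwise
#'   subjects are pooled
#' @return named integer vector (pooled mode), including zero counts for
#'   vocabulary tissues without observations; in subject mode a tibble with
#'   columns `subject_id`, `tissue`, `n_peptides`
#' @export
count_per_tissue <- function(catalog, by_subject = FALSE) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  obs <- catalog$observations
  if (by_subject) {
    out <- dplyr::summarise(
      dplyr::group_by(obs, .data$subject_id, .data$tissue),
      n_peptides = dplyr::n_distinct(.data$sequence), .groups = "drop")
    return(out)
  }
  counts <- stats::setNames(integer(length(catalog$tissues)), catalog$tissues)
  tab <- tapply(obs$sequence, obs$tissue, function(s) length(unique(s)))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Tissue connectivity matrix
#'
#' For every pair of tissues, the number of peptides detected in both (a
#' peptide counts as present in a tissue if any aggregated observation with
#' an intensity exists there, pooling subjects). The diagonal holds the
#' number of peptides detected ONLY in that tissue (tissue-specific counts),
#' not the tissue total.
#'
#' @param catalog a [peptide_catalog()]
#' @return symmetric integer matrix, tissues x tissues
#' @export
connectivity <- function(catalog) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  tissues <- catalog$tissues
  if (length(tissues) < 1) stop("catalog has no tissues", call. = FALSE)
  obs <- unique(catalog$observations[, c("sequence", "tissue")])
  # peptide x tissue incidence
  inc <- table(factor(obs$sequence), factor(obs$tissue, levels = tissues)) > 0
  inc <- matrix(as.numeric(inc), nrow = nrow(inc), dimnames = dimnames(inc))
  m <- t(inc) %*% inc
  breadth <- rowSums(inc)
  diag(m) <- vapply(tissues, function(t) {
    sum(inc[, t] == 1 & breadth == 1)
  }, numeric(1))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(tissues, tissues)
  m
}

#' Partition the repertoire into tissue-specific and core-shared peptides
#'
#' Tissue-specific peptides are detected in exactly one tissue; core-shared
#' peptides are detected in every tissue of `core_tissues`. Fractions are
#' reported raw and formatted (integer percent, one decimal below 2%).
#'
#' @param catalog a [peptide_catalog()]
#' @param core_tissues optional character vector of tissues defining the
#'   shared core (e.g. spleen, bone marrow, kidney, lung, liver, colon)
#' @return list with `total` (distinct peptides), `tissue_specific`
#'   (sequences, per-peptide tissue, and a [report_fraction()]) and, when
#'   `core_tissues` is given, `shared_core` likewise
#' @export
partition_specificity <- function(catalog, core_tissues = NULL) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  obs <- unique(catalog$observations[, c("sequence", "tissue")])
  tissues_per_pep <- split(obs$tissue, obs$sequence)
  total <- length(tissues_per_pep)
  breadth <- lengths(tissues_per_pep)
  spec_seqs <- names(tissues_per_pep)[breadth == 1]
  out <- list(
    total = total,
    tissue_specific = list(
      peptides = spec_seqs,
      tissue = vapply(tissues_per_pep[spec_seqs], `[`, character(1), 1),
      fraction = report_fraction(length(spec_seqs), max(total, 1L))
    )
  )
  if (!is.null(core_tissues)) {
    unknown <- setdiff(core_tissues, catalog$tissues)
    if (length(unknown) > 0) {
      stop("unknown core tissue(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    shared <- names(tissues_per_pep)[vapply(
      tissues_per_pep, function(tt) all(core_tissues %in% tt), logical(1))]
    out$shared_core <- list(
      peptides = shared, core_tissues = core_tissues,
      fraction = report_fraction(length(shared), max(total, 1L))
    )
  }
  out
}

#' Principal component analysis of tissue immunopeptidomes
#'
#' Each tissue is represented by the vector of log10 peptide intensities
#' (mean log10 intensity across subjects where a peptide was detected more
#' than once); peptides not detected in a tissue contribute 0. Variables
#' (peptides) are centered and, by default, unit-scaled before the
#' eigendecomposition; zero-variance peptides are dropped when scaling.
#'
#' @param catalog a [peptide_catalog()]
#' @param scale_unit unit-scale peptide variables (default `TRUE`)
#' @return list with `coordinates` (tibble: tissue, PC1, PC2),
#'   `var_explained` (shares per component, non-increasing) and `metadata`
#' @export
pca_tissues <- function(catalog, scale_unit = TRUE) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  tissues <- catalog$tissues
  if (length(tissues) < 3) {
    stop("tissue PCA requires at least 3 tissues", call. = FALSE)
  }
  obs <- catalog$observations
  if (length(unique(obs$sequence)) < 2) {
    stop("tissue PCA requires at least 2 peptides", call. = FALSE)
  }
  agg <- dplyr::summarise(
    dplyr::group_by(obs, .data$sequence, .data$tissue),
    value = mean(log10(.data$intensity)), .groups = "drop")
  peptides <- sort(unique(agg$sequence))
  x <- matrix(0, nrow = length(tissues), ncol = length(peptides),
              dimnames = list(tissues, peptides))
  x[cbind(agg$tissue, agg$sequence)] <- agg$value
  if (scale_unit) {
    keep <- apply(x, 2, stats::sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_unit)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    coordinates = tibble::tibble(tissue = rownames(pc$x),
                                 PC1 = pc$x[, 1],
                                 PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0),
    var_explained = shares,
    metadata = list(scale_unit = scale_unit, n_peptides = ncol(x),
                    imputation = "undetected = 0 after log10 of detected")
  )
}

#' Presentation breadth versus abundance and affinity
#'
#' For each peptide: breadth (number of tissues where detected), mean log10
#' intensity, and best (minimum) rank score. Spearman rank correlations of
#' breadth against both properties are reported with two-sided p-values
#' (breadth is an integer, heavily tied scale, so a rank correlation is
#' used).
#'
#' @param catalog a [peptide_catalog()]
#' @return list with `records` (tibble: sequence, breadth,
#'   mean_log10_intensity, best_rank), `intensity` and `rank` (each a list
#'   with `rho`, `p_value`), and `degenerate` flag when breadth is constant
#' @export
breadth_vs_property <- function(catalog) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  obs <- catalog$observations
  per_tissue <- unique(obs[, c("sequence", "tissue")])
  breadth <- table(per_tissue$sequence)
  rec <- dplyr::summarise(
    dplyr::group_by(obs, .data$sequence),
    mean_log10_intensity = mean(log10(.data$intensity)),
    best_rank = min(.data$rank_score), .groups = "drop")
  rec$breadth <- as.integer(breadth[rec$sequence])
  rec <- rec[, c("sequence", "breadth", "mean_log10_intensity", "best_rank")]
  degenerate <- length(unique(rec$breadth)) < 2
  cor_one <- function(y) {
    if (degenerate || length(unique(y)) < 2) {
      return(list(rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(rec$breadth, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  }
  list(records = rec,
       intensity = cor_one(rec$mean_log10_intensity),
       rank = cor_one(rec$best_rank),
       degenerate = degenerate)
}

#' Cross-species comparison of per-tissue peptide counts
#'
#' Matches tissues between two atlases via an explicit name map and reports
#' the ordinary least-squares R-squared of the matched counts.
#'
#' @param counts_a,counts_b named numeric vectors of per-tissue counts
#' @param tissue_name_map named character vector mapping names of `counts_a`
#'   tissues to names of `counts_b` tissues; identity for common names if
#'   `NULL`
#' @return list with `r_squared`, `n_matched`, and the matched tibble
#' @export
cross_species_counts <- function(counts_a, counts_b, tissue_name_map = NULL) {
  if (is.null(tissue_name_map)) {
    common <- intersect(names(counts_a), names(counts_b))
    tissue_name_map <- stats::setNames(common, common)
  }
  a_names <- names(tissue_name_map)
  matched <- a_names[a_names %in% names(counts_a) &
                     tissue_name_map %in% names(counts_b)]
  if (length(matched) < 3) {
    stop("cross-species comparison requires at least 3 matched tissue pairs",
         call. = FALSE)
  }
  x <- counts_a[matched]
  y <- counts_b[tissue_name_map[matched]]
  r2 <- stats::cor(x, y)^2
  list(r_squared = unname(r2), n_matched = length(matched),
       matched = tibble::tibble(tissue_a = matched,
                                tissue_b = unname(tissue_name_map[matched]),
                                count_a = unname(x), count_b = unname(y)))
}
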