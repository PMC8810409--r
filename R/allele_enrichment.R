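# Subject-level allotype share and fold-enrichment statistics across
# tissues, with cross-subject averaging and threshold flagging.

#' Per-tissue allotype shares for one subject
#'
#' For each tissue with at least one allele-assigned peptide, the share of
#' that tissue's assigned peptides carried by each of the subject's alleles.
#' Unassigned peptides are excluded from the denominator; tissues with zero
#' assigned peptides are omitted.
#'
#' @param catalog a [peptide_catalog()]
#' @param subject subject identifier
#' @param min_assigned warn when a tissue has fewer assigned peptides than
#'   this floor (shares from thin tissues are noisy)
#' @return tibble with columns `subject_id`, `allele`, `tissue`, `share`,
#'   `n_assigned` (assigned peptides in the tissue); shares within a
#'   (subject, tissue) sum to 1
#' @export
allele_shares <- function(catalog, subject, min_assigned = 50L) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  if (!subject %in% catalog$subjects) {
    stop("unknown subject: ", subject, call. = FALSE)
  }
  obs <- catalog$observations
  obs <- obs[obs$subject_id == subject & !is.na(obs$allele), , drop = FALSE]
  if (nrow(obs) == 0) {
    stop("subject ", subject, " has no allele-assigned peptides", call. = FALSE)
  }
  alleles <- catalog$subject_alleles[[subject]]
  per_tissue <- dplyr::summarise(
    dplyr::group_by(obs, .data$tissue),
    n_assigned = dplyr::n_distinct(.data$sequence), .groups = "drop")
  thin <- per_tissue$tissue[per_tissue$n_assigned < min_assigned]
  if (length(thin) > 0) {
    atlas_log("subject ", subject, ": tissue(s) with < ", min_assigned,
              " assigned peptides: ", paste(thin, collapse = ", "),
              level = "warn")
  }
  grid <- tidyr::expand_grid(allele = alleles, tissue = per_tissue$tissue)
  counts <- dplyr::summarise(
    dplyr::group_by(obs, .data$allele, .data$tissue),
    n = dplyr::n_distinct(.data$sequence), .groups = "drop")
  out <- dplyr::left_join(grid, counts, by = c("allele", "tissue"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::left_join(out, per_tissue, by = "tissue")
  out$share <- out$n / out$n_assigned
  tibble::tibble(subject_id = subject, allele = out$allele,
                 tissue = out$tissue, share = out$share,
                 n_assigned = out$n_assigned)
}

#' Tissue-dependent allotype fold enrichment
#'
#' Converts shares into fold enrichments per (allele, tissue). In the
#' default `exclusive` mode the focal tissue's share is divided by the mean
#' share over the remaining tissues (the worked examples' convention: a 55%
#' colon share against a 22% mean elsewhere gives 2.5-fold). In `inclusive`
#' mode the denominator is the mean over all tissues including the focal
#' one, in which case each allele's enrichments average exactly 1 across
#' tissues. A zero denominator yields `Inf` with `flag_infinite` set.
#'
#' @param shares tibble from [allele_shares()]
#' @param mode `"exclusive"` (default) or `"inclusive"`
#' @return tibble with columns `subject_id`, `allele`, `tissue`, `share`,
#'   `enrichment`, `n_tissues`, `mode`, `flag_infinite`
#' @export
enrichment <- function(shares, mode = c("exclusive", "inclusive")) {
  mode <- match.arg(mode)
  sh <- tibble::as_tibble(shares)
  stopifnot(all(c("subject_id", "allele", "tissue", "share") %in% names(sh)))
  n_tis <- length(unique(sh$tissue))
  if (n_tis < 2) {
    stop("enrichment requires shares over at least 2 tissues", call. = FALSE)
  }
  out <- dplyr::mutate(
    dplyr::group_by(sh, .data$subject_id, .data$allele),
    n_tissues = dplyr::n(),
    denom = if (mode == "inclusive") mean(.data$share)
            else (sum(.data$share) - .data$share) / (dplyr::n() - 1),
    enrichment = ifelse(.data$denom == 0,
                        ifelse(.data$share == 0, NA_real_, Inf),
                        .data$share / .data$denom)
  )
  out <- dplyr::ungroup(out)
  out$flag_infinite <- is.infinite(out$enrichment)
  if (any(out$flag_infinite)) {
    atlas_log(sum(out$flag_infinite),
              " enrichment value(s) infinite (allele absent in other tissues)",
              level = "warn")
  }
  out$mode <- mode
  out[, c("subject_id", "allele", "tissue", "share", "enrichment",
          "n_tissues", "mode", "flag_infinite")]
}

#' Average enrichments across subjects and flag over-represented pairs
#'
#' Arithmetic mean of per-subject enrichments for each (allele, tissue) over
#' the subjects carrying that allele; pairs whose mean is at or above the
#' threshold are flagged as over-represented.
#'
#' @param tables one enrichment tibble (from [enrichment()]) or a list of
#'   them, one per subject
#' @param threshold flagging threshold on the mean fold enrichment
#'   (default 1.5)
#' @return list with `table` (tibble: allele, tissue, mean_enrichment,
#'   n_subjects, flagged) and `summary` (n_flagged, n_alleles_flagged,
#'   n_tissues_flagged)
#' @export
average_and_flag <- function(tables, threshold = 1.5) {
  if (!is.data.frame(tables)) tables <- dplyr::bind_rows(tables)
  if (nrow(tables) == 0) stop("no enrichment tables supplied", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive number", call. = FALSE)
  }
  tab <- dplyr::summarise(
    dplyr::group_by(tables, .data$allele, .data$tissue),
    mean_enrichment = mean(.data$enrichment[!is.na(.data$enrichment)]),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    .groups = "drop")
  tab$flagged <- !is.na(tab$mean_enrichment) & tab$mean_enrichment >= threshold
  flagged <- tab[tab$flagged, , drop = FALSE]
  list(
    table = tab,
    summary = list(
      n_flagged = nrow(flagged),
      n_alleles_flagged = length(unique(flagged$allele)),
      n_tissues_flagged = length(unique(flagged$tissue)),
      threshold = threshold)
  )
}
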