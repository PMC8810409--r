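# Domain types and file I/O. Every analysis module consumes only the types
# constructed here, so catalogs behave identically whether read from disk or
# generated synthetically.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default tissue synonym map
#'
#' Maps alternative tissue names to a canonical term so mouse and human
#' vocabularies line up (e.g. the human term "Myelon" and the mouse term
#' "Spinal cord" denote the same organ). Names are the synonyms, values the
#' canonical terms; extend or replace via the `synonyms` argument of
#' [read_peptide_table()].
#'
#' @return named character vector
#' @export
tissue_synonyms <- function() {
  c("Myelon" = "Spinal cord")
}

#' Default column mapping for peptide observation tables
#'
#' @return named character vector mapping internal field names to the column
#'   headers expected in the TSV.
#' @export
peptide_columns <- function() {
  c(sequence = "sequence", subject = "subject", tissue = "tissue",
    allele = "allele", rank = "rank", intensity = "intensity",
    source_genes = "source_genes")
}

#' Construct a peptide catalog
#'
#' A catalog holds aggregated peptide observations across tissues and
#' subjects. Duplicate (sequence, tissue, subject) rows are aggregated:
#' intensity keeps the maximum (pulldown depths are heterogeneous, so a
#' rank-preserving, non-additive rule is used), rank keeps the best
#' (minimum), the allele follows the best-rank row, and source genes are
#' unioned.
#'
#' @param observations tibble/data.frame with columns `sequence`,
#'   `subject_id`, `tissue`, `allele` (NA = unassigned), `rank_score`,
#'   `intensity`, and optionally `source_genes` (list column of character
#'   vectors, or a `;`-separated character column)
#' @param tissues optional ordered tissue vocabulary; defaults to the sorted
#'   tissues observed
#' @param subject_alleles optional named list, subject -> character vector of
#'   class I alleles; defaults to the alleles observed per subject
#' @param species one of `"mouse"`, `"human"`, or `NA`; human catalogs are
#'   checked for at most six class I alleles per subject
#' @return object of class `peptide_catalog`: a list with `observations`,
#'   `tissues`, `subjects`, `subject_alleles`, `species`
#' @export
peptide_catalog <- function(observations, tissues = NULL,
                            subject_alleles = NULL, species = NA_character_) {
  obs <- tibble::as_tibble(observations)
  required <- c("sequence", "subject_id", "tissue", "rank_score", "intensity")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    stop("peptide observations lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"allele" %in% names(obs)) obs$allele <- NA_character_
  if (!"source_genes" %in% names(obs)) {
    obs$source_genes <- replicate(nrow(obs), character(0), simplify = FALSE)
  }
  if (is.character(obs$source_genes)) {
    obs$source_genes <- lapply(obs$source_genes, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }

  bad_seq <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                    obs$sequence)
  if (any(bad_seq)) {
    stop("invalid peptide sequence(s) (must be uppercase 20-letter amino-acid ",
         "strings), e.g. row ", which(bad_seq)[1], ": ",
         obs$sequence[which(bad_seq)[1]], call. = FALSE)
  }
  bad_int <- !is.finite(obs$intensity) | obs$intensity <= 0
  if (any(bad_int)) {
    stop("non-positive or missing intensity in row(s) ",
         paste(utils::head(which(bad_int), 5), collapse = ", "), call. = FALSE)
  }
  if (any(obs$rank_score < 0, na.rm = TRUE)) {
    stop("rank_score must be >= 0", call. = FALSE)
  }

  obs <- aggregate_observations(obs)

  if (is.null(tissues)) tissues <- sort(unique(obs$tissue))
  unknown <- setdiff(obs$tissue, tissues)
  if (length(unknown) > 0) {
    stop("tissue(s) outside the catalog vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  subjects <- sort(unique(obs$subject_id))
  if (is.null(subject_alleles)) {
    subject_alleles <- lapply(subjects, function(s) {
      sort(unique(stats::na.omit(obs$allele[obs$subject_id == s])))
    })
    names(subject_alleles) <- subjects
  }
  if (identical(species, "human")) {
    n_alleles <- vapply(subject_alleles, length, integer(1))
    if (any(n_alleles > 6)) {
      stop("human subjects carry at most 6 class I alleles; violated by: ",
           paste(names(subject_alleles)[n_alleles > 6], collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(observations = obs, tissues = tissues, subjects = subjects,
         subject_alleles = subject_alleles, species = species),
    class = "peptide_catalog"
  )
}

# Aggregate duplicate (sequence, tissue, subject) rows: max intensity,
# best (minimum) rank, allele of the best-rank row, union of source genes.
aggregate_observations <- function(obs) {
  key <- paste(obs$sequence, obs$tissue, obs$subject_id, sep = "\r")
  if (!anyDuplicated(key)) {
    return(dplyr::arrange(obs, .data$sequence, .data$subject_id, .data$tissue))
  }
  split_idx <- split(seq_len(nrow(obs)), key)
  rows <- lapply(split_idx, function(idx) {
    sub <- obs[idx, , drop = FALSE]
    best <- which.min(ifelse(is.na(sub$rank_score), Inf, sub$rank_score))
    if (!is.finite(min(sub$rank_score, na.rm = FALSE)) && all(is.na(sub$rank_score))) best <- 1L
    out <- sub[best, , drop = FALSE]
    out$intensity <- max(sub$intensity)
    out$rank_score <- suppressWarnings(min(sub$rank_score, na.rm = TRUE))
    if (!is.finite(out$rank_score)) out$rank_score <- NA_real_
    out$source_genes <- list(sort(unique(unlist(sub$source_genes))))
    out
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$sequence, .data$subject_id, .data$tissue)
}

#' @export
print.peptide_catalog <- function(x, ...) {
  cat(sprintf(
    "peptide_catalog: %d observations | %d distinct peptides | %d tissues | %d subject(s)%s\n",
    nrow(x$observations), length(unique(x$observations$sequence)),
    length(x$tissues), length(x$subjects),
    if (is.na(x$species)) "" else paste0(" | species: ", x$species)))
  invisible(x)
}

#' Read a peptide observation table
#'
#' Reads a tab-delimited table of peptide observations (one row per peptide
#' per tissue per subject, mirroring published atlas supplementary tables),
#' normalizes tissue names through a synonym map, and aggregates duplicate
#' (sequence, tissue, subject) rows.
#'
#' @param path TSV file with a header row
#' @param species_mode `"mouse"` or `"human"`
#' @param columns named character vector mapping internal field names to file
#'   column headers; see [peptide_columns()]
#' @param synonyms tissue synonym map; see [tissue_synonyms()]
#' @return a [peptide_catalog()]
#' @export
read_peptide_table <- function(path, species_mode = c("mouse", "human"),
                               columns = peptide_columns(),
                               synonyms = tissue_synonyms()) {
  species_mode <- match.arg(species_mode)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("sequence", "subject", "tissue", "allele", "rank", "intensity")
  for (field in mandatory) {
    if (!columns[[field]] %in% names(raw)) {
      stop("peptide table is missing mandatory column '", columns[[field]],
           "' (field: ", field, ")", call. = FALSE)
    }
  }
  has_genes <- columns[["source_genes"]] %in% names(raw)
  obs <- tibble::tibble(
    sequence = raw[[columns[["sequence"]]]],
    subject_id = raw[[columns[["subject"]]]],
    tissue = raw[[columns[["tissue"]]]],
    allele = dplyr::na_if(raw[[columns[["allele"]]]], ""),
    rank_score = as.numeric(raw[[columns[["rank"]]]]),
    intensity = as.numeric(raw[[columns[["intensity"]]]]),
    source_genes = if (has_genes) raw[[columns[["source_genes"]]]] else
      NA_character_
  )
  if (nrow(obs) > 0) {
    hit <- obs$tissue %in% names(synonyms)
    obs$tissue[hit] <- unname(synonyms[obs$tissue[hit]])
  }
  peptide_catalog(obs, species = species_mode)
}

#' Write a peptide catalog to TSV
#'
#' Inverse of [read_peptide_table()]; rows are written in deterministic
#' (sequence, subject, tissue) order so identical catalogs produce identical
#' files.
#'
#' @param catalog a [peptide_catalog()]
#' @param path output path
#' @export
write_peptide_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  obs <- catalog$observations
  out <- tibble::tibble(
    sequence = obs$sequence, subject = obs$subject_id, tissue = obs$tissue,
    allele = ifelse(is.na(obs$allele), "", obs$allele),
    rank = format(obs$rank_score, digits = 15, trim = TRUE, scientific = FALSE),
    intensity = format(obs$intensity, digits = 15, trim = TRUE, scientific = FALSE),
    source_genes = vapply(obs$source_genes, paste, character(1), collapse = ";")
  )
  out <- dplyr::arrange(out, .data$sequence, .data$subject, .data$tissue)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gene x tissue or protein x tissue abundance matrix
#'
#' First column holds identifiers, remaining columns tissues. For
#' `kind = "protein"` an optional `molecular_weight` column (Da) is detached
#' into an attribute, and zero abundances are converted to missing (a
#' label-free intensity of zero denotes non-detection).
#'
#' @param path TSV file
#' @param kind `"expression"` (TPM, zeros allowed) or `"protein"`
#'   (label-free intensity, non-missing values must be positive)
#' @param missing_tokens strings interpreted as missing values
#' @return numeric matrix (identifiers x tissues); protein matrices carry a
#'   `molecular_weight` attribute (named numeric, Da) when present in the file
#' @export
read_matrix <- function(path, kind = c("expression", "protein"),
                        missing_tokens = default_missing_tokens()) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate identifier(s) in matrix: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  mw <- NULL
  value_cols <- names(raw)[-1]
  if (kind == "protein" && "molecular_weight" %in% value_cols) {
    mw <- as.numeric(raw[["molecular_weight"]])
    names(mw) <- ids
    value_cols <- setdiff(value_cols, "molecular_weight")
  }
  vals <- vapply(value_cols, function(cn) {
    v <- raw[[cn]]
    v[v %in% missing_tokens] <- NA_character_
    as.numeric(v)
  }, numeric(nrow(raw)))
  if (nrow(raw) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, value_cols))
  rownames(vals) <- ids
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative values are not valid ", kind, " abundances", call. = FALSE)
  }
  if (kind == "protein") {
    n_zero <- sum(vals == 0, na.rm = TRUE)
    if (n_zero > 0) {
      atlas_log(n_zero, " zero protein intensities treated as missing")
      vals[vals == 0] <- NA_real_
    }
    if (!is.null(mw)) attr(vals, "molecular_weight") <- mw
  }
  vals
}

#' Write an abundance matrix to TSV
#'
#' @param mat numeric matrix with row and column names
#' @param path output path
#' @param id_name header for the identifier column
#' @export
write_matrix <- function(mat, path, id_name = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  ord <- order(rownames(mat))
  out <- tibble::as_tibble(mat[ord, , drop = FALSE])
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(),
    ~ ifelse(is.na(.x), NA_character_,
             format(.x, digits = 15, trim = TRUE, scientific = FALSE))))
  out <- dplyr::bind_cols(tibble::tibble(!!id_name := rownames(mat)[ord]), out)
  mw <- attr(mat, "molecular_weight")
  if (!is.null(mw)) {
    out$molecular_weight <- format(unname(mw[rownames(mat)[ord]]), digits = 15,
                                   trim = TRUE, scientific = FALSE)
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read gene models from a BED file
#'
#' Accepts BED6 (whole gene as a single exon) or BED12 (exon blocks). The
#' file uses the native BED convention (0-based, half-open); models are kept
#' in the same convention internally. The transcription start site is the
#' first transcribed base: the interval start on `+` genes and the last base
#' (`end - 1`) on `-` genes. Overlapping exon blocks are merged into their
#' union with a warning.
#'
#' @param path BED file
#' @return tibble with columns `gene_id`, `chrom`, `strand`, `tss` (0-based
#'   position) and `exons` (list of two-column matrices `start`,`end`,
#'   0-based half-open)
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    return(tibble::tibble(gene_id = character(0), chrom = character(0),
                          strand = character(0), tss = integer(0),
                          exons = list()))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("gene models require an explicit strand (+ or -)", call. = FALSE)
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  has_blocks <- "blocks" %in% names(S4Vectors::mcols(gr))
  exons <- lapply(seq_along(gr), function(i) {
    if (has_blocks) {
      bl <- S4Vectors::mcols(gr)$blocks[[i]]
      ex <- cbind(start = start0[i] + IRanges::start(bl) - 1L,
                  end = start0[i] + IRanges::end(bl))
    } else {
      ex <- cbind(start = start0[i], end = end0[i])
    }
    merge_intervals(ex, warn_id = S4Vectors::mcols(gr)$name[i])
  })
  tibble::tibble(
    gene_id = S4Vectors::mcols(gr)$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand, tss = as.integer(tss), exons = exons
  )
}

# Merge overlapping half-open intervals into their union (sorted).
merge_intervals <- function(ex, warn_id = NULL) {
  stopifnot(all(ex[, "start"] < ex[, "end"]))
  if (nrow(ex) <= 1) return(ex)
  ir <- IRanges::IRanges(start = ex[, "start"] + 1L, end = ex[, "end"])
  red <- IRanges::reduce(ir)
  if (length(red) < length(ir)) {
    warning("overlapping exon intervals merged",
            if (!is.null(warn_id)) paste0(" for gene ", warn_id) else "",
            call. = FALSE)
  }
  cbind(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

#' Write gene models to a BED12 file
#'
#' @param models tibble as returned by [read_gene_models()]
#' @param path output path
#' @export
write_gene_models <- function(models, path) {
  models <- dplyr::arrange(models, .data$chrom, .data$gene_id)
  lines <- vapply(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    ex <- ex[order(ex[, "start"]), , drop = FALSE]
    g_start <- min(ex[, "start"]); g_end <- max(ex[, "end"])
    paste(models$chrom[i], g_start, g_end, models$gene_id[i], 0,
          models$strand[i], g_start, g_end, "0,0,0", nrow(ex),
          paste0(paste(ex[, "end"] - ex[, "start"], collapse = ","), ","),
          paste0(paste(ex[, "start"] - g_start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base conservation track from bedGraph
#'
#' Scores are per-base conservation probabilities in [0, 1] (PhastCons
#' style); bases not covered by any bedGraph interval are missing.
#'
#' @param path bedGraph file (0-based, half-open intervals)
#' @return object of class `conservation_track`: a named list, one numeric
#'   vector per chromosome, position `i` (0-based) stored at index `i + 1`,
#'   `NA` marking uncovered bases
#' @export
read_conservation <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  score <- S4Vectors::mcols(gr)$score
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("conservation scores must lie in [0, 1]", call. = FALSE)
  }
  chroms <- as.character(GenomicRanges::seqnames(gr))
  track <- lapply(split(seq_along(gr), chroms), function(idx) {
    len <- max(GenomicRanges::end(gr)[idx])
    v <- rep(NA_real_, len)
    for (i in idx) {
      v[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- score[i]
    }
    v
  })
  structure(track, class = "conservation_track")
}

#' Write a conservation track to bedGraph
#'
#' @param track a `conservation_track`
#' @param path output path
#' @export
write_conservation <- function(track, path) {
  stopifnot(inherits(track, "conservation_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in sort(names(track))) {
    v <- track[[chrom]]
    covered <- !is.na(v)
    if (!any(covered)) next
    r <- rle(paste0(covered, "\r", ifelse(covered, format(v, digits = 10), "")))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- covered[starts]
    df <- data.frame(chrom = chrom, start = starts[keep] - 1L,
                     end = ends[keep],
                     score = format(v[starts[keep]], digits = 10, trim = TRUE,
                                    scientific = FALSE))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Extract per-base values from a conservation track
#'
#' @param track a `conservation_track`
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @return numeric vector of length `end - start` (`NA` = missing)
#' @export
track_values <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "conservation_track"), start >= 0, end > start)
  v <- track[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom, call. = FALSE)
  if (end > length(v)) {
    stop("interval [", start, ", ", end, ") extends beyond track on ", chrom,
         call. = FALSE)
  }
  v[(start + 1L):end]
}
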