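# Small in-code fixtures shared across test files.

options(mhcatlas.quiet = TRUE)

# One observation row per element of `tissues`.
obs_rows <- function(seq, subject, tissues, allele = "AL01", rank = 0.5,
                     intensity = 100, genes = character(0)) {
  tibble::tibble(sequence = seq, subject_id = subject, tissue = tissues,
                 allele = allele, rank_score = rank, intensity = intensity,
                 source_genes = replicate(length(tissues), genes,
                                          simplify = FALSE))
}

# Catalog with peptides P1:{T1}, P2:{T1,T2}, P3:{T2,T3}.
toy_connectivity_catalog <- function() {
  peptide_catalog(dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "s1", "T1"),
    obs_rows("CCCCCCCCC", "s1", c("T1", "T2")),
    obs_rows("DDDDDDDDD", "s1", c("T2", "T3"))))
}

# Brute-force pairwise intersection connectivity for cross-checking.
brute_connectivity <- function(catalog) {
  tissues <- catalog$tissues
  obs <- unique(catalog$observations[, c("sequence", "tissue")])
  sets <- lapply(tissues, function(t) obs$sequence[obs$tissue == t])
  names(sets) <- tissues
  m <- matrix(0L, length(tissues), length(tissues),
              dimnames = list(tissues, tissues))
  for (i in tissues) for (j in tissues) {
    if (i == j) {
      others <- unique(obs$sequence[obs$tissue != i])
      m[i, j] <- length(setdiff(sets[[i]], others))
    } else {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

# Exhaustive sliding-window oracle for region scores.
brute_region_score <- function(v, window = 12L) {
  if (all(is.na(v))) return(NA_real_)
  if (length(v) < window) return(mean(v, na.rm = TRUE))
  means <- vapply(seq_len(length(v) - window + 1L), function(i) {
    w <- v[i:(i + window - 1L)]
    if (any(is.na(w))) NA_real_ else mean(w)
  }, numeric(1))
  if (all(is.na(means))) return(mean(v, na.rm = TRUE))
  max(means, na.rm = TRUE)
}

# A conservation track directly from a numeric vector.
track_from_vector <- function(v, chrom = "chr1") {
  structure(stats::setNames(list(v), chrom), class = "conservation_track")
}
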