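# Synthetic multi-tissue, multi-subject cohorts with planted ground truth.
# The generator emulates the statistical structure of published atlas data
# (expression-coupled detection, universal and tissue-restricted genes,
# allotype-enriched tissues, abundance-correlated proteins, class-dependent
# conservation) so every analysis stage can be tested without downloads.

#' Configuration of a synthetic cohort
#'
#' Defaults describe a desk-scale cohort: 10 tissues; a mouse-style design
#' has one pooled subject with two class I alleles, a human-style design
#' three donors with six alleles each. Genes fall into three classes:
#' universal-source genes (high expression in all tissues; each contributes
#' one peptide forced detected everywhere), tissue-restricted genes (high
#' expression in exactly one home tissue; each contributes one peptide
#' detected only there), and background genes. All remaining peptides are
#' detected by a logistic model whose log-odds rise with log10 expression
#' and fall with binding rank.
#'
#' @param species `"mouse"` or `"human"`
#' @param n_tissues number of tissues
#' @param n_subjects number of subjects (forced to 1 in mouse mode)
#' @param alleles_per_subject class I alleles per subject (2 mouse, up to 6
#'   human)
#' @param n_genes named counts per class: `universal`, `tissue_restricted`,
#'   `background`
#' @param peptides_per_gene mean peptides per gene (Poisson, minimum 1)
#' @param detection logistic detection parameters `intercept`,
#'   `expr_slope` (per log10(TPM+1)), `rank_slope` (per rank unit)
#' @param intensity log-normal intensity parameters `meanlog`, `sdlog`,
#'   `expr_coef` (per log10(TPM+1))
#' @param conservation per-class Beta parameters (shape1, shape2) for
#'   per-base exon conservation
#' @param promoter_conservation Beta parameters for promoter bases; `NULL`
#'   reuses `conservation`
#' @param n_planted_enriched number of planted (allele, tissue) enrichment
#'   pairs; each multiplies that allele's detection odds in that tissue for
#'   every subject carrying the allele
#' @param enriched_fold detection-odds multiplier of planted pairs
#' @param n_planted_correlated number of background proteins whose log10
#'   abundance is linear in the per-tissue peptide count
#' @param correlated_effect planted effect size: log10-abundance change per
#'   standard deviation of the per-tissue count vector
#' @param correlated_noise_sd Gaussian noise sd (log10 units) around the
#'   planted line
#' @param seed RNG seed; a fixed seed makes the cohort fully reproducible
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(species = c("mouse", "human"), n_tissues = 10L,
                          n_subjects = NULL, alleles_per_subject = NULL,
                          n_genes = c(universal = 10L,
                                      tissue_restricted = 30L,
                                      background = 600L),
                          peptides_per_gene = 4,
                          detection = c(intercept = -3, expr_slope = 1.2,
                                        rank_slope = -0.5),
                          intensity = c(meanlog = 4, sdlog = 1,
                                        expr_coef = 1),
                          conservation = list(universal = c(8, 2),
                                              tissue_restricted = c(2, 8),
                                              background = c(2, 5)),
                          promoter_conservation = NULL,
                          n_planted_enriched = 1L, enriched_fold = 3,
                          n_planted_correlated = 20L,
                          correlated_effect = 0.5,
                          correlated_noise_sd = 0.15,
                          seed = 1L) {
  species <- match.arg(species)
  # tolerate YAML-style named lists for vector-valued parameters
  n_genes <- unlist(n_genes)
  detection <- unlist(detection)
  intensity <- unlist(intensity)
  conservation <- lapply(conservation, unlist)
  if (!is.null(promoter_conservation)) {
    promoter_conservation <- lapply(promoter_conservation, unlist)
  }
  if (species == "mouse") {
    n_subjects <- 1L
    alleles_per_subject <- alleles_per_subject %||% 2L
  } else {
    n_subjects <- n_subjects %||% 3L
    alleles_per_subject <- alleles_per_subject %||% 6L
    if (alleles_per_subject > 6) {
      stop("human subjects carry at most 6 class I alleles", call. = FALSE)
    }
  }
  stopifnot(n_tissues >= 1, n_subjects >= 1, alleles_per_subject >= 1,
            all(n_genes >= 0), peptides_per_gene >= 1,
            enriched_fold > 0, n_planted_correlated >= 0,
            correlated_noise_sd >= 0)
  if (n_planted_enriched > alleles_per_subject * n_tissues) {
    stop("more planted enriched pairs (", n_planted_enriched,
         ") than allele x tissue cells (",
         alleles_per_subject * n_tissues, ")", call. = FALSE)
  }
  if (n_planted_correlated > n_genes[["background"]]) {
    stop("more planted correlated proteins than background genes",
         call. = FALSE)
  }
  structure(list(
    species = species, n_tissues = as.integer(n_tissues),
    n_subjects = as.integer(n_subjects),
    alleles_per_subject = as.integer(alleles_per_subject),
    n_genes = n_genes, peptides_per_gene = peptides_per_gene,
    detection = detection, intensity = intensity,
    conservation = conservation,
    promoter_conservation = promoter_conservation %||% conservation,
    n_planted_enriched = as.integer(n_planted_enriched),
    enriched_fold = enriched_fold,
    n_planted_correlated = as.integer(n_planted_correlated),
    correlated_effect = correlated_effect,
    correlated_noise_sd = correlated_noise_sd,
    seed = as.integer(seed)), class = "cohort_config")
}

random_peptides <- function(lengths) {
  seqs <- vapply(lengths, function(l) {
    paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
  }, character(1))
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(lengths[dup], function(l) {
      paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
    }, character(1))
  }
  seqs
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces a peptide catalog, a gene x tissue expression matrix (TPM), a
#' protein x tissue abundance matrix with molecular weights, gene models on
#' a single pseudo-chromosome, a per-base conservation track, and the
#' machine-readable truth of everything planted. The same seed yields
#' byte-identical outputs.
#'
#' @param config a [cohort_config()]
#' @return list of class `synthetic_cohort` with elements `catalog`,
#'   `expression`, `protein`, `gene_models`, `conservation`, `truth`,
#'   `config`
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::local_seed(config$seed)

  tissues <- sprintf("Tissue%02d", seq_len(config$n_tissues))
  if (config$species == "mouse") {
    subjects <- "mouse"
    subject_alleles <- list(mouse = c("H2-Db", "H2-Kb")[
      seq_len(min(2, config$alleles_per_subject))])
    if (config$alleles_per_subject > 2) {
      subject_alleles$mouse <- c(subject_alleles$mouse,
                                 sprintf("H2-X%d", seq_len(config$alleles_per_subject - 2)))
    }
  } else {
    subjects <- sprintf("D%02d", seq_len(config$n_subjects))
    pool <- sprintf("AL%02d",
                    seq_len(config$alleles_per_subject + config$n_subjects))
    subject_alleles <- lapply(subjects, function(s) {
      sort(sample(pool, config$alleles_per_subject))
    })
    names(subject_alleles) <- subjects
  }

  # --- genes and expression -------------------------------------------------
  n_uni <- config$n_genes[["universal"]]
  n_ts <- config$n_genes[["tissue_restricted"]]
  n_bg <- config$n_genes[["background"]]
  n_gene <- n_uni + n_ts + n_bg
  gene_ids <- sprintf("gene%04d", seq_len(n_gene))
  gene_class <- rep(c("universal-source", "tissue-restricted", "background"),
                    times = c(n_uni, n_ts, n_bg))
  names(gene_class) <- gene_ids
  home_tissue <- stats::setNames(rep(NA_character_, n_gene), gene_ids)
  if (n_ts > 0) {
    home_tissue[gene_class == "tissue-restricted"] <-
      rep(tissues, length.out = n_ts)
  }

  expr <- matrix(0, nrow = n_gene, ncol = length(tissues),
                 dimnames = list(gene_ids, tissues))
  for (i in seq_len(n_gene)) {
    expr[i, ] <- switch(
      gene_class[i],
      "universal-source" = stats::rlnorm(length(tissues), log(500), 0.3),
      "tissue-restricted" = {
        v <- stats::rlnorm(length(tissues), log(1), 0.5)
        v[tissues == home_tissue[i]] <- stats::rlnorm(1, log(300), 0.3)
        v
      },
      "background" = stats::rlnorm(1, log(20), 1) *
        stats::rlnorm(length(tissues), 0, 0.3))
  }

  # --- peptides -------------------------------------------------------------
  n_pep_per_gene <- 1L + stats::rpois(n_gene, config$peptides_per_gene - 1)
  pep_gene <- rep(gene_ids, n_pep_per_gene)
  first_of_gene <- !duplicated(pep_gene)
  pep_kind <- ifelse(first_of_gene & gene_class[pep_gene] == "universal-source",
                     "planted_universal",
              ifelse(first_of_gene & gene_class[pep_gene] == "tissue-restricted",
                     "planted_ts", "ordinary"))
  planted <- pep_kind != "ordinary"
  pep_len <- ifelse(planted, sample(8:12, length(pep_gene), replace = TRUE),
                    sample(7:13, length(pep_gene), replace = TRUE))
  pep_rank <- ifelse(planted, stats::runif(length(pep_gene), 0, 2),
                     stats::runif(length(pep_gene), 0, 5))
  pep_seq <- random_peptides(pep_len)
  n_pep <- length(pep_seq)

  # --- planted enrichment pairs --------------------------------------------
  all_alleles <- sort(unique(unlist(subject_alleles)))
  enriched_pairs <- NULL
  if (config$n_planted_enriched > 0) {
    cells <- tidyr::expand_grid(allele = all_alleles, tissue = tissues)
    pick <- cells[sample.int(nrow(cells), config$n_planted_enriched), ,
                  drop = FALSE]
    enriched_pairs <- dplyr::bind_rows(lapply(seq_len(nrow(pick)), function(i) {
      carriers <- subjects[vapply(subject_alleles,
                                  function(a) pick$allele[i] %in% a,
                                  logical(1))]
      if (length(carriers) == 0) carriers <- subjects[1]
      tibble::tibble(subject_id = carriers, allele = pick$allele[i],
                     tissue = pick$tissue[i], fold = config$enriched_fold)
    }))
  }

  # --- detection and intensities -------------------------------------------
  det <- config$detection
  intens <- config$intensity
  log_expr <- log10(expr[pep_gene, , drop = FALSE] + 1)  # peptide x tissue
  obs_list <- list()
  for (s in subjects) {
    alleles_s <- subject_alleles[[s]]
    pep_allele <- sample(alleles_s, n_pep, replace = TRUE)
    logit <- det[["intercept"]] + det[["expr_slope"]] * log_expr +
      det[["rank_slope"]] * pep_rank
    odds <- exp(logit)
    if (!is.null(enriched_pairs)) {
      ep <- enriched_pairs[enriched_pairs$subject_id == s, , drop = FALSE]
      for (i in seq_len(nrow(ep))) {
        rows <- pep_allele == ep$allele[i]
        odds[rows, ep$tissue[i]] <- odds[rows, ep$tissue[i]] * ep$fold[i]
      }
    }
    p <- odds / (1 + odds)
    u <- matrix(stats::runif(n_pep * length(tissues)), nrow = n_pep)
    detected <- u < p
    detected[pep_kind == "planted_universal", ] <- TRUE
    ts_rows <- which(pep_kind == "planted_ts")
    detected[ts_rows, ] <- FALSE
    detected[cbind(ts_rows, match(home_tissue[pep_gene[ts_rows]], tissues))] <- TRUE
    noise <- matrix(stats::rnorm(n_pep * length(tissues)), nrow = n_pep)
    log_int <- intens[["meanlog"]] + intens[["expr_coef"]] * log_expr +
      intens[["sdlog"]] * noise
    idx <- which(detected, arr.ind = TRUE)
    obs_list[[s]] <- tibble::tibble(
      sequence = pep_seq[idx[, 1]],
      subject_id = s,
      tissue = tissues[idx[, 2]],
      allele = pep_allele[idx[, 1]],
      rank_score = pep_rank[idx[, 1]],
      intensity = exp(log_int[idx]),
      source_genes = as.list(pep_gene[idx[, 1]]))
  }
  obs <- dplyr::bind_rows(obs_list)
  catalog <- peptide_catalog(obs, tissues = tissues,
                             subject_alleles = subject_alleles,
                             species = config$species)

  # --- gene models and conservation track ----------------------------------
  exon_len <- 100L; n_exons <- 3L; intron_len <- 80L
  body_len <- n_exons * exon_len + (n_exons - 1L) * intron_len
  margin <- 2200L
  gene_start <- margin + (seq_len(n_gene) - 1L) * (body_len + 2L * margin)
  strand <- rep(c("+", "-"), length.out = n_gene)
  models <- tibble::tibble(
    gene_id = gene_ids, chrom = "chrS", strand = strand,
    tss = as.integer(ifelse(strand == "+", gene_start,
                            gene_start + body_len - 1L)),
    exons = lapply(seq_len(n_gene), function(i) {
      starts <- gene_start[i] + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
      cbind(start = as.integer(starts), end = as.integer(starts + exon_len))
    }))
  chrom_len <- gene_start[n_gene] + body_len + margin
  track_v <- rep(NA_real_, chrom_len)
  beta_for <- function(params, n) stats::rbeta(n, params[1], params[2])
  class_key <- c("universal-source" = "universal",
                 "tissue-restricted" = "tissue_restricted",
                 "background" = "background")
  for (i in seq_len(n_gene)) {
    key <- class_key[[gene_class[i]]]
    ex <- models$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      track_v[(ex[j, "start"] + 1L):ex[j, "end"]] <-
        beta_for(config$conservation[[key]], exon_len)
    }
    pr <- promoter_region(models[i, ])
    track_v[(pr$start + 1L):pr$end] <-
      beta_for(config$promoter_conservation[[key]],
               pr$end - pr$start)
  }
  track <- structure(list(chrS = track_v), class = "conservation_track")

  # --- protein abundances ---------------------------------------------------
  counts <- count_per_tissue(filter_binders(catalog))
  correlated <- NULL
  base <- stats::rnorm(n_gene, 6, 0.8)
  log_ab <- base + matrix(stats::rnorm(n_gene * length(tissues), 0, 0.3),
                          nrow = n_gene)
  dimnames(log_ab) <- list(gene_ids, tissues)
  if (config$n_planted_correlated > 0) {
    bg_ids <- gene_ids[gene_class == "background"]
    planted_prot <- sort(sample(bg_ids, config$n_planted_correlated))
    signs <- sample(c(-1, 1), config$n_planted_correlated, replace = TRUE)
    count_sd <- stats::sd(counts)
    if (count_sd == 0) count_sd <- 1
    z_counts <- (counts - mean(counts)) / count_sd
    for (i in seq_along(planted_prot)) {
      log_ab[planted_prot[i], ] <- 6 +
        signs[i] * config$correlated_effect * z_counts +
        stats::rnorm(length(tissues), 0, config$correlated_noise_sd)
    }
    correlated <- tibble::tibble(
      protein_id = planted_prot, sign = signs,
      slope = signs * config$correlated_effect / count_sd)
  }
  protein <- 10^log_ab
  attr(protein, "molecular_weight") <- stats::setNames(
    stats::rlnorm(n_gene, log(5e4), 0.4), gene_ids)

  truth <- list(
    universal_peptides = pep_seq[pep_kind == "planted_universal"],
    tissue_specific_peptides = stats::setNames(
      home_tissue[pep_gene[pep_kind == "planted_ts"]],
      pep_seq[pep_kind == "planted_ts"]),
    enriched_pairs = enriched_pairs,
    correlated_proteins = correlated,
    gene_class = gene_class)

  structure(list(catalog = catalog, expression = expr, protein = protein,
                 gene_models = models, conservation = track, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the same file formats the readers in this package consume
#' (peptide TSV, matrix TSVs, BED12 gene models, bedGraph conservation)
#' plus the planted truth as TSV files.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()]
#' @param outdir output directory (created if absent)
#' @return `outdir`, invisibly
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_peptide_table(cohort$catalog, p("peptides.tsv"))
  write_matrix(cohort$expression, p("expression.tsv"), id_name = "gene_id")
  write_matrix(cohort$protein, p("protein.tsv"), id_name = "protein_id")
  write_gene_models(cohort$gene_models, p("genes.bed"))
  write_conservation(cohort$conservation, p("conservation.bedGraph"))
  tr <- cohort$truth
  readr::write_tsv(tibble::tibble(sequence = sort(tr$universal_peptides)),
                   p("truth_universal.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(sequence = names(tr$tissue_specific_peptides),
                   tissue = unname(tr$tissue_specific_peptides)) |>
      dplyr::arrange(.data$sequence),
    p("truth_tissue_specific.tsv"), progress = FALSE)
  if (!is.null(tr$enriched_pairs)) {
    readr::write_tsv(tr$enriched_pairs, p("truth_enriched.tsv"),
                     progress = FALSE)
  }
  if (!is.null(tr$correlated_proteins)) {
    readr::write_tsv(tr$correlated_proteins, p("truth_correlated.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(tibble::tibble(gene_id = names(tr$gene_class),
                                  class = unname(tr$gene_class)),
                   p("truth_gene_class.tsv"), progress = FALSE)
  invisible(outdir)
}

#' Generate an independent null dataset for screen calibration
#'
#' Protein abundances and per-tissue peptide counts are drawn independently
#' of each other, so any regression passing the screen thresholds is a
#' false positive; used to calibrate the expected false-positive fraction
#' of the proteome screen.
#'
#' @param n_proteins number of pseudo-proteins
#' @param n_tissues number of tissues (>= 3)
#' @param seed RNG seed
#' @return list with `protein` (matrix, arbitrary abundance units) and
#'   `counts` (named per-tissue pseudo peptide counts)
#' @export
generate_null_screen <- function(n_proteins, n_tissues, seed = 1L) {
  if (n_tissues < 3) stop("null screen requires n_tissues >= 3", call. = FALSE)
  withr::local_seed(seed)
  tissues <- sprintf("Tissue%02d", seq_len(n_tissues))
  mat <- 10^matrix(stats::rnorm(n_proteins * n_tissues, 6, 0.5),
                   nrow = n_proteins, ncol = n_tissues,
                   dimnames = list(if (n_proteins > 0)
                     sprintf("null%05d", seq_len(n_proteins)) else NULL,
                     tissues))
  counts <- stats::setNames(stats::rpois(n_tissues, 500), tissues)
  list(protein = mat, counts = counts)
}
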