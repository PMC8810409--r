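# End-to-end orchestration: simulate or load, filter, landscape statistics,
# allotype enrichment, expression linkage, universal selection and
# conservation, proteome screen; one machine-readable run report.

#' Run the full atlas analysis pipeline
#'
#' Stages run in dependency order; a stage whose inputs are unavailable is
#' skipped with an explicit report entry, and a stage failure marks the run
#' failed. Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param config a named list or path to a YAML file with entries:
#'   \describe{
#'     \item{simulate}{list passed to [cohort_config()] (or `TRUE` for
#'       defaults); mutually exclusive with `inputs`}
#'     \item{inputs}{list of paths: `peptides`, `expression`, `protein`,
#'       `genes`, `conservation`}
#'     \item{species}{`"mouse"` or `"human"`}
#'     \item{seed}{integer seed recorded in the report and used for every
#'       stochastic stage}
#'     \item{outdir}{output directory}
#'     \item{filter, enrichment, universal, screen}{optional per-stage
#'       parameter lists (`min_len`, `max_len`, `rank_max`; `mode`,
#'       `threshold`; `min_tissues_per_donor`, `top_k`; `r2_min`, `p_max`,
#'       `min_pairs`, `permutations`)}
#'   }
#' @param outdir overrides `config$outdir`
#' @return the run report (named list), invisibly written as
#'   `report.json` in `outdir` together with all stage output tables
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  outdir <- outdir %||% config$outdir %||% stop("outdir required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  species <- config$species %||% "mouse"
  seed <- as.integer(config$seed %||% 1L)
  report <- list(package_version = as.character(utils::packageVersion("mhcatlas")),
                 species = species, seed = seed, stages = list())
  p <- function(f) file.path(outdir, f)
  note <- function(stage, status, ...) {
    report$stages[[stage]] <<- c(list(status = status), list(...))
    atlas_log("stage ", stage, ": ", status)
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      note(stage, "failed", error = conditionMessage(e))
      report$failed <<- TRUE
      NULL
    })
  }

  # --- load or simulate -----------------------------------------------------
  cohort <- NULL; catalog <- NULL; expression <- NULL; protein <- NULL
  models <- NULL; track <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- if (isTRUE(config$simulate)) list() else config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    sim_args$species <- sim_args$species %||% species
    cohort <- run_stage("simulate", function() {
      do.call(cohort_config, sim_args) |> generate_cohort()
    })
    if (is.null(cohort)) return(finish_report(report, p))
    write_cohort(cohort, file.path(outdir, "cohort"))
    catalog <- cohort$catalog; expression <- cohort$expression
    protein <- cohort$protein; models <- cohort$gene_models
    track <- cohort$conservation; truth <- cohort$truth
    note("simulate", "ok", n_observations = nrow(catalog$observations))
  } else {
    inputs <- config$inputs %||% stop("config needs 'simulate' or 'inputs'")
    for (path in unlist(inputs)) {
      if (!file.exists(path)) stop("input path does not exist: ", path)
    }
    catalog <- run_stage("load", function() {
      read_peptide_table(inputs$peptides, species_mode = species)
    })
    if (is.null(catalog)) return(finish_report(report, p))
    if (!is.null(inputs$expression)) {
      expression <- read_matrix(inputs$expression, "expression")
    }
    if (!is.null(inputs$protein)) {
      protein <- read_matrix(inputs$protein, "protein")
    }
    if (!is.null(inputs$genes)) models <- read_gene_models(inputs$genes)
    if (!is.null(inputs$conservation)) {
      track <- read_conservation(inputs$conservation)
    }
    note("load", "ok", n_observations = nrow(catalog$observations))
  }

  # --- binder filter --------------------------------------------------------
  fpar <- config$filter %||% list()
  filtered <- run_stage("filter", function() {
    filter_binders(catalog, min_len = fpar$min_len %||% 8L,
                   max_len = fpar$max_len %||% 12L,
                   rank_max = fpar$rank_max %||% 2.0)
  })
  if (is.null(filtered)) return(finish_report(report, p))
  write_peptide_table(filtered, p("filtered_peptides.tsv"))
  note("filter", "ok", n_before = nrow(catalog$observations),
       n_after = nrow(filtered$observations))

  # --- landscape ------------------------------------------------------------
  run_stage("landscape", function() {
    counts <- count_per_tissue(filtered)
    readr::write_tsv(tibble::tibble(tissue = names(counts),
                                    n_peptides = as.integer(counts)),
                     p("per_tissue_counts.tsv"), progress = FALSE)
    conn <- connectivity(filtered)
    write_matrix(conn, p("connectivity.tsv"), id_name = "tissue")
    part <- partition_specificity(filtered)
    bre <- breadth_vs_property(filtered)
    readr::write_tsv(bre$records, p("breadth_records.tsv"), progress = FALSE)
    pca <- tryCatch(pca_tissues(filtered), error = function(e) NULL)
    if (!is.null(pca)) {
      readr::write_tsv(pca$coordinates, p("pca_coordinates.tsv"),
                       progress = FALSE)
    }
    note("landscape", "ok",
         tissue_specific_fraction = part$tissue_specific$fraction$percent,
         tissue_specific_label = part$tissue_specific$fraction$label,
         breadth_intensity_rho = bre$intensity$rho,
         pc1_share = if (is.null(pca)) NA else pca$var_explained[1])
  })

  # --- allotype enrichment --------------------------------------------------
  epar <- config$enrichment %||% list()
  run_stage("enrichment", function() {
    tables <- lapply(filtered$subjects, function(s) {
      enrichment(allele_shares(filtered, s),
                 mode = epar$mode %||% "exclusive")
    })
    avg <- average_and_flag(tables, threshold = epar$threshold %||% 1.5)
    readr::write_tsv(avg$table, p("enrichment.tsv"), progress = FALSE)
    note("enrichment", "ok", n_flagged = avg$summary$n_flagged,
         n_alleles_flagged = avg$summary$n_alleles_flagged,
         n_tissues_flagged = avg$summary$n_tissues_flagged)
  })

  # --- expression linkage ---------------------------------------------------
  if (is.null(expression)) {
    note("linkage", "skipped", reason = "no expression matrix supplied")
  } else {
    run_stage("linkage", function() {
      cls <- classify_genes(filtered, expression)
      readr::write_tsv(cls$table, p("gene_classes.tsv"), progress = FALSE)
      z <- zscore_matrix(filtered, expression)
      write_matrix(z, p("zscore_matrix.tsv"), id_name = "source_tissue")
      note("linkage", "ok", unmapped_fraction = cls$unmapped_fraction,
           p_any_vs_none = cls$tests$any_vs_none)
    })
  }

  # --- universal selection and conservation ---------------------------------
  upar <- config$universal %||% list()
  universal <- run_stage("universal", function() {
    sel <- select_universal(
      filtered, species_mode = species,
      min_tissues_per_donor = upar$min_tissues_per_donor %||% 14L,
      top_k = upar$top_k %||% 100L)
    readr::write_tsv(tibble::tibble(sequence = sel$peptides),
                     p("universal_peptides.tsv"), progress = FALSE)
    note("universal", "ok", n_universal = length(sel$peptides),
         universal_fraction = sel$fraction$percent,
         universal_label = sel$fraction$label)
    sel
  })
  if (is.null(models) || is.null(track)) {
    note("conservation", "skipped",
         reason = "gene models or conservation track missing")
  } else if (!is.null(universal)) {
    run_stage("conservation", function() {
      part <- partition_specificity(filtered)
      obs <- filtered$observations
      ts_genes <- unique(unlist(
        obs$source_genes[obs$sequence %in% part$tissue_specific$peptides]))
      ts_genes <- setdiff(ts_genes, universal$source_genes)
      uni_models <- models[models$gene_id %in% universal$source_genes, ]
      ts_models <- models[models$gene_id %in% ts_genes, ]
      su <- score_gene_regions(uni_models, track)
      st <- score_gene_regions(ts_models, track)
      readr::write_tsv(dplyr::bind_rows(
        dplyr::mutate(su, group = "universal"),
        dplyr::mutate(st, group = "tissue_specific")),
        p("conservation_scores.tsv"), progress = FALSE)
      cmp <- compare_conservation(su, st)
      note("conservation", "ok",
           p_promoter = cmp$promoter$p_value %||% NA,
           p_exon = cmp$exon$p_value %||% NA)
    })
  }

  # --- proteome screen ------------------------------------------------------
  spar <- config$screen %||% list()
  if (is.null(protein)) {
    note("screen", "skipped", reason = "no protein abundance matrix supplied")
  } else {
    run_stage("screen", function() {
      cfg <- screen_config(species = species,
                           r2_min = spar$r2_min %||% 0.4,
                           p_max = spar$p_max,
                           min_pairs = spar$min_pairs %||% 10L)
      counts <- if (species == "mouse") {
        count_per_tissue(filtered)
      } else {
        by_subj <- count_per_tissue(filtered, by_subject = TRUE)
        lapply(stats::setNames(filtered$subjects, filtered$subjects),
               function(s) {
                 sub <- by_subj[by_subj$subject_id == s, ]
                 stats::setNames(sub$n_peptides, sub$tissue)
               })
      }
      scr <- run_screen(protein, counts, cfg)
      readr::write_tsv(scr$hits, p("screen_hits.tsv"), progress = FALSE)
      cal <- calibrate_fp(protein,
                          if (is.list(counts)) counts[[1]] else counts,
                          n_permutations = spar$permutations %||% 200L,
                          seed = seed, r2_min = cfg$r2_min,
                          min_pairs = cfg$min_pairs)
      recall <- NA_real_
      if (!is.null(truth) && !is.null(truth$correlated_proteins)) {
        planted <- truth$correlated_proteins$protein_id
        recall <- mean(planted %in% scr$hits$protein_id)
      }
      note("screen", "ok", n_hits = scr$summary$n_hits,
           n_positive = scr$summary$n_positive,
           n_negative = scr$summary$n_negative,
           fp_fraction_r2 = cal$fp_fraction_r2,
           planted_recall = recall)
    })
  }

  finish_report(report, p)
}

finish_report <- function(report, p) {
  report$failed <- isTRUE(report$failed)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(report)
}
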