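test_that("mouse universal peptides must appear in every tissue", {
  tissues <- paste0("T", 1:5)
  obs <- dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "mouse", tissues),
    obs_rows("CCCCCCCCC", "mouse", tissues[-1]))
  cat <- peptide_catalog(obs, tissues = tissues)
  sel <- select_universal(cat, "mouse")
  expect_equal(sel$peptides, "AAAAAAAAA")
  expect_equal(sel$fraction$fraction, 0.5)
  multi <- peptide_catalog(dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "D1", "T1"), obs_rows("AAAAAAAAA", "D2", "T1")))
  expect_error(select_universal(multi, "mouse"), "single pooled subject")
})

test_that("human criteria c1-c3 select by completeness, allele and frequency", {
  tis <- function(n) paste0("T", seq_len(n))
  obs <- dplyr::bind_rows(
    # D1 and D2 sample 3 tissues each (threshold lowered for the toy)
    obs_rows("AAAAAAAAA", "D1", tis(3)), obs_rows("AAAAAAAAA", "D2", tis(3)),
    obs_rows("CCCCCCCCC", "D1", tis(2), allele = "AL02"),
    obs_rows("DDDDDDDDD", "D2", tis(1)),
    obs_rows("EEEEEEEEE", "D1", tis(2)))
  cat <- peptide_catalog(obs, species = "human")
  sel <- select_universal(cat, "human", min_tissues_per_donor = 3,
                          top_k = 1, min_allele_samples = 2)
  expect_true("AAAAAAAAA" %in% sel$peptides)   # c1 (and c2, c3)
  expect_false("DDDDDDDDD" %in% sel$peptides)
  crit <- sel$criteria[sel$criteria$sequence == "AAAAAAAAA", ]
  expect_true(crit$c1 && crit$c2 && crit$c3)
})

test_that("frequency ties at the top-k rank are all selected", {
  obs <- dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "D1", paste0("T", 1:3)),
    obs_rows("CCCCCCCCC", "D1", paste0("T", 1:2)),
    obs_rows("DDDDDDDDD", "D1", paste0("T", 2:3)),
    obs_rows("EEEEEEEEE", "D1", "T1"))
  cat <- peptide_catalog(obs, species = "human")
  sel <- select_universal(cat, "human", min_tissues_per_donor = 3,
                          top_k = 2, min_allele_samples = 99)
  # frequencies 3,2,2,1: rank-2 cutoff is 2, both tied peptides kept
  expect_equal(sel$n_c3_selected, 3)
})

test_that("promoter intervals are strand-aware and clipped", {
  g <- tibble::tibble(gene_id = c("gp", "gm", "gc"), chrom = "chr1",
                      strand = c("+", "-", "+"),
                      tss = c(10000L, 10000L, 500L))
  pr <- promoter_region(g)
  expect_equal(pr$start, c(8000L, 9800L, 0L))
  expect_equal(pr$end, c(10200L, 12000L, 700L))
})

test_that("region scores follow the sliding-window rules", {
  expect_equal(region_conservation(track_from_vector(rep(0.3, 50)),
                                   "chr1", 0, 50), 0.3, tolerance = 1e-12)
  v14 <- c(0, 0, rep(1, 12))
  expect_equal(region_conservation(track_from_vector(v14), "chr1", 0, 14),
               1.0, tolerance = 1e-12)
  expect_equal(region_conservation(track_from_vector(rep(0.5, 8)),
                                   "chr1", 0, 8), 0.5)
  expect_true(is.na(region_conservation(
    track_from_vector(rep(NA_real_, 20)), "chr1", 0, 20)))
})

test_that("region scores equal the exhaustive-window oracle", {
  set.seed(31)
  for (i in 1:20) {
    v <- stats::rbeta(200, 2, 3)
    v[sample.int(200, 15)] <- NA
    expect_equal(region_conservation(track_from_vector(v), "chr1", 0, 200),
                 brute_region_score(v), tolerance = 1e-12)
  }
  # translation invariance
  v <- stats::rbeta(100, 2, 2)
  tr <- track_from_vector(c(rep(NA, 37), v, rep(NA, 5)))
  expect_equal(region_conservation(tr, "chr1", 37, 137),
               region_conservation(track_from_vector(v), "chr1", 0, 100),
               tolerance = 1e-12)
})

test_that("conservation comparison reproduces exact rank-sum p-values", {
  mk <- function(scores) tibble::tibble(gene_id = seq_along(scores),
                                        feature = "promoter",
                                        score = scores)
  res <- compare_conservation(mk(c(0.1, 0.2, 0.3)), mk(c(0.7, 0.8, 0.9)))
  expect_equal(res$promoter$p_value, 0.1, tolerance = 1e-12)
  same <- compare_conservation(mk(c(0.1, 0.2, 0.3)), mk(c(0.1, 0.2, 0.3)))
  expect_equal(same$promoter$p_value, 1)
  expect_true(all(abs(same$promoter$cdf$universal -
                        same$promoter$cdf$tissue_specific) < 1e-12))
})

test_that("planted conservation classes separate at extreme significance", {
  cohort <- generate_cohort(cohort_config(
    n_genes = c(universal = 200, tissue_restricted = 200, background = 50),
    n_planted_correlated = 10, seed = 19))
  cls <- cohort$truth$gene_class
  models <- cohort$gene_models
  su <- score_gene_regions(models[models$gene_id %in%
                                    names(cls)[cls == "universal-source"], ],
                           cohort$conservation)
  st <- score_gene_regions(models[models$gene_id %in%
                                    names(cls)[cls == "tissue-restricted"], ],
                           cohort$conservation)
  cmp <- compare_conservation(su, st)
  expect_lt(cmp$promoter$p_value, 1e-10)
  expect_lt(cmp$exon$p_value, 1e-10)
  # universal scores stochastically dominate: CDF lies below
  cdf <- cmp$exon$cdf
  expect_true(all(cdf$universal <= cdf$tissue_specific + 1e-12))
})

test_that("universal and tissue-specific peptide sets are disjoint", {
  cohort <- generate_cohort(cohort_config(seed = 23))
  cat <- filter_binders(cohort$catalog)
  sel <- select_universal(cat, "mouse")
  part <- partition_specificity(cat)
  expect_length(intersect(sel$peptides, part$tissue_specific$peptides), 0)
})
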