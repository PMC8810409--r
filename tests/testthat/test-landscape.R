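test_that("binder filter keeps 8-12mers with rank at or below the cutoff", {
  obs <- dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "s1", "T1", rank = 2.0),    # 9-mer, boundary rank
    obs_rows("CCCCCCC", "s1", "T1", rank = 0.1),      # 7-mer out
    obs_rows("DDDDDDDDDDDDD", "s1", "T1", rank = 0.1),# 13-mer out
    obs_rows("EEEEEEEE", "s1", "T1", rank = 2.01),    # rank out
    obs_rows("FFFFFFFFFFFF", "s1", "T1", rank = 1.9), # 12-mer in
    obs_rows("GGGGGGGG", "s1", "T1", rank = 0.0))     # 8-mer in
  f <- filter_binders(peptide_catalog(obs))
  expect_setequal(f$observations$sequence,
                  c("AAAAAAAAA", "FFFFFFFFFFFF", "GGGGGGGG"))
})

test_that("filtering is idempotent", {
  cat <- filter_binders(generate_cohort(cohort_config(
    n_genes = c(universal = 3, tissue_restricted = 5, background = 30),
    n_planted_correlated = 5, seed = 3))$catalog)
  expect_identical(filter_binders(cat)$observations, cat$observations)
})

test_that("best-allele assignment is argmin with lexicographic ties", {
  rt <- tibble::tibble(
    sequence = c("P1", "P1", "P2", "P2", "P3"),
    allele = c("A*02:01", "B*07:02", "Y", "X", "Z"),
    rank_score = c(0.3, 1.8, 0.5, 0.5, 1.0))
  out <- assign_best_allele(rt)
  expect_equal(out$allele[out$sequence == "P1"], "A*02:01")
  expect_equal(out$allele[out$sequence == "P2"], "X")
  expect_equal(out$allele[out$sequence == "P3"], "Z")
})

test_that("per-tissue counts include empty vocabulary tissues", {
  cat <- toy_connectivity_catalog()
  cat$tissues <- c(cat$tissues, "T4")
  counts <- count_per_tissue(cat)
  expect_equal(counts[["T1"]], 2)
  expect_equal(counts[["T2"]], 2)
  expect_equal(counts[["T4"]], 0)
})

test_that("connectivity matches hand-enumerated sets on the toy catalog", {
  m <- connectivity(toy_connectivity_catalog())
  expect_true(isSymmetric(m))
  expect_equal(m["T1", "T2"], 1L)
  expect_equal(m["T2", "T3"], 1L)
  expect_equal(m["T1", "T3"], 0L)
  expect_equal(unname(diag(m)), c(1L, 0L, 0L))
})

test_that("connectivity equals brute-force pairwise intersections", {
  cohort <- generate_cohort(cohort_config(
    n_genes = c(universal = 5, tissue_restricted = 10, background = 60),
    n_planted_correlated = 5, seed = 11))
  cat <- filter_binders(cohort$catalog)
  expect_lt(length(unique(cat$observations$sequence)), 1000)
  expect_equal(connectivity(cat), brute_connectivity(cat))
})

test_that("tissue-unique plus shared counts reconstruct tissue totals", {
  cat <- filter_binders(generate_cohort(cohort_config(seed = 4))$catalog)
  m <- connectivity(cat)
  counts <- count_per_tissue(cat)
  obs <- unique(cat$observations[, c("sequence", "tissue")])
  breadth <- table(obs$sequence)
  for (t in cat$tissues) {
    seqs <- obs$sequence[obs$tissue == t]
    shared_elsewhere <- sum(breadth[seqs] > 1)
    expect_equal(m[t, t] + shared_elsewhere, unname(counts[t]))
  }
})

test_that("specificity partition reports correct sets and fractions", {
  cat <- toy_connectivity_catalog()
  part <- partition_specificity(cat, core_tissues = c("T1", "T2"))
  expect_setequal(part$tissue_specific$peptides, "AAAAAAAAA")
  expect_equal(part$shared_core$peptides, "CCCCCCCCC")
  expect_equal(part$tissue_specific$fraction$fraction, 1 / 3)
  expect_error(partition_specificity(cat, core_tissues = "T9"), "unknown")
})

test_that("tissue PCA matches a direct eigendecomposition oracle", {
  obs <- dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "s1", c("T1", "T2", "T3"),
             intensity = c(10, 100, 1000)),
    obs_rows("CCCCCCCCC", "s1", c("T1", "T2", "T3"),
             intensity = c(20, 200, 2000)),
    obs_rows("DDDDDDDDD", "s1", c("T1", "T2", "T3"),
             intensity = c(1000, 100, 10)))
  cat <- peptide_catalog(obs)
  res <- pca_tissues(cat, scale_unit = FALSE)
  # tissues as observations, peptides as variables
  x <- cbind(log10(c(10, 100, 1000)), log10(c(20, 200, 2000)),
             log10(c(1000, 100, 10)))
  ev <- eigen(stats::cov(x))$values
  expect_equal(res$var_explained[1], ev[1] / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(res$var_explained) <= 1e-12))
})

test_that("PCA coordinates are invariant (up to sign) to row order", {
  cohort <- generate_cohort(cohort_config(
    n_genes = c(universal = 5, tissue_restricted = 10, background = 40),
    n_planted_correlated = 5, seed = 8))
  cat <- cohort$catalog
  res1 <- pca_tissues(cat)
  cat2 <- cat
  perm <- rev(seq_len(nrow(cat$observations)))
  cat2$observations <- cat$observations[perm, ]
  res2 <- pca_tissues(cat2)
  expect_equal(abs(res1$coordinates$PC1), abs(res2$coordinates$PC1),
               tolerance = 1e-8)
  expect_equal(res1$var_explained, res2$var_explained, tolerance = 1e-9)
})

test_that("breadth correlations match a rank-correlation oracle", {
  obs <- dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "s1", "T1", intensity = 10, rank = 1.9),
    obs_rows("CCCCCCCCC", "s1", c("T1", "T2"), intensity = 40, rank = 1.2),
    obs_rows("DDDDDDDDD", "s1", c("T1", "T2", "T3"), intensity = 90,
             rank = 0.8),
    obs_rows("EEEEEEEEE", "s1", "T2", intensity = 15, rank = 1.5),
    obs_rows("FFFFFFFFF", "s1", c("T2", "T3"), intensity = 60, rank = 0.4),
    obs_rows("GGGGGGGGG", "s1", c("T1", "T2", "T3"), intensity = 80,
             rank = 0.3))
  res <- breadth_vs_property(peptide_catalog(obs))
  rec <- res$records
  oracle <- stats::cor(rank(rec$breadth), rank(rec$mean_log10_intensity))
  expect_equal(res$intensity$rho, oracle, tolerance = 1e-9)
  expect_gt(res$intensity$rho, 0)
})

test_that("synthetic cohorts show the breadth-abundance trend", {
  cat <- filter_binders(generate_cohort(cohort_config(seed = 21))$catalog)
  res <- breadth_vs_property(cat)
  expect_gt(res$intensity$rho, 0)
  expect_lt(res$intensity$p_value, 0.01)
})

test_that("cross-species count comparison computes OLS R-squared", {
  a <- c(T1 = 1, T2 = 2, T3 = 3)
  b <- c(U1 = 2, U2 = 4, U3 = 6)
  map <- c(T1 = "U1", T2 = "U2", T3 = "U3")
  expect_equal(cross_species_counts(a, b, map)$r_squared, 1, tolerance = 1e-12)
  a4 <- c(T1 = 1, T2 = 2, T3 = 3, T4 = 4)
  b4 <- c(T1 = 1, T2 = 3, T3 = 2, T4 = 4)
  expect_equal(cross_species_counts(a4, b4)$r_squared, 0.64,
               tolerance = 1e-12)
  expect_error(cross_species_counts(a[1:2], b4), "3 matched")
})
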