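test_that("per-protein fits equal the lm oracle", {
  set.seed(41)
  tissues <- paste0("T", 1:12)
  for (i in 1:10) {
    ab <- stats::setNames(10^stats::rnorm(12, 6, 0.5), tissues)
    ab[sample.int(12, 1)] <- NA
    y <- stats::setNames(stats::rpois(12, 300) +
                           5 * log10(ifelse(is.na(ab), 1, ab)), tissues)
    fit <- fit_protein(ab, y)
    keep <- !is.na(ab)
    ref <- stats::lm(y[keep] ~ log10(ab[keep]))
    s <- summary(ref)
    expect_equal(fit$slope, unname(stats::coef(ref)[2]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(stats::coef(ref)[1]),
                 tolerance = 1e-9)
    expect_equal(fit$r_squared, s$r.squared, tolerance = 1e-9)
    expect_equal(fit$p_value, s$coefficients[2, 4], tolerance = 1e-9)
  }
})

test_that("matrix fits agree with the scalar path and honor min_pairs", {
  set.seed(43)
  tissues <- paste0("T", 1:11)
  mat <- matrix(10^stats::rnorm(5 * 11, 6, 0.4), nrow = 5,
                dimnames = list(paste0("p", 1:5), tissues))
  mat[1, 1:2] <- NA           # 9 pairs -> rejected
  mat[2, ] <- 100             # zero variance -> degenerate
  counts <- stats::setNames(stats::rpois(11, 400), tissues)
  fits <- fit_abundance_matrix(mat, counts, min_pairs = 10)
  expect_equal(fits$status[1], "insufficient_pairs")
  expect_true(is.na(fits$r_squared[1]))
  expect_equal(fits$status[2], "degenerate")
  for (i in 3:5) {
    ref <- fit_protein(mat[i, ], counts)
    expect_equal(fits$r_squared[i], ref$r_squared, tolerance = 1e-9)
    expect_equal(fits$p_value[i], ref$p_value, tolerance = 1e-9)
    expect_equal(fits$slope[i], ref$slope, tolerance = 1e-9)
  }
})

test_that("perfectly linear data give R-squared one and 9 pairs are refused", {
  tissues <- paste0("T", 1:10)
  ab <- stats::setNames(10^seq(5, 6.8, length.out = 10), tissues)
  y <- stats::setNames(2 * log10(ab) + 1, tissues)
  fit <- fit_protein(ab, y)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$direction, "positive")
  expect_equal(fit_protein(ab[1:9], y[1:9])$status, "insufficient_pairs")
})

test_that("screen statistics are invariant to row order and abundance rescaling", {
  null <- generate_null_screen(50, 10, seed = 47)
  f1 <- fit_abundance_matrix(null$protein, null$counts)
  perm <- sample.int(50)
  f2 <- fit_abundance_matrix(null$protein[perm, ], null$counts)
  f2 <- f2[match(f1$protein_id, f2$protein_id), ]
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  f3 <- fit_abundance_matrix(null$protein * 1000, null$counts)
  expect_equal(f1$r_squared, f3$r_squared, tolerance = 1e-9)
  expect_equal(f1$p_value, f3$p_value, tolerance = 1e-9)
  expect_equal(f1$slope, f3$slope, tolerance = 1e-9)
})

test_that("human mode requires replication across subjects", {
  set.seed(53)
  tissues <- paste0("T", 1:12)
  counts1 <- stats::setNames(stats::rpois(12, 300), tissues)
  mat <- matrix(10^stats::rnorm(3 * 12, 6, 0.3), nrow = 3,
                dimnames = list(paste0("p", 1:3), tissues))
  # p1 tracks subject D1 counts only; p2 tracks a shared signal
  shared <- stats::setNames(stats::rpois(12, 300), tissues)
  mat[1, ] <- 10^(5 + 0.004 * counts1)
  mat[2, ] <- 10^(5 + 0.004 * shared)
  counts <- list(D1 = counts1, D2 = shared, D3 = shared)
  res <- run_screen(mat, counts, screen_config("human"))
  expect_false("p1" %in% res$hits$protein_id)
  expect_true("p2" %in% res$hits$protein_id)
})

test_that("planted correlated proteins are recovered with few false hits", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  cat <- filter_binders(cohort$catalog)
  counts <- count_per_tissue(cat)
  res <- run_screen(cohort$protein, counts, screen_config("mouse"))
  planted <- cohort$truth$correlated_proteins$protein_id
  expect_gte(mean(planted %in% res$hits$protein_id), 0.8)
  nulls <- setdiff(rownames(cohort$protein), planted)
  expect_lte(mean(nulls %in% res$hits$protein_id), 0.05)
  signs <- cohort$truth$correlated_proteins$sign
  hit_dir <- res$hits$direction[match(planted, res$hits$protein_id)]
  recovered <- !is.na(hit_dir)
  expect_true(all(hit_dir[recovered] ==
                    ifelse(signs[recovered] > 0, "positive", "negative")))
})

test_that("tissue merging averages the mapped columns", {
  mat <- matrix(c(10, 30, 5, 7), nrow = 1,
                dimnames = list("p1", c("Jejunum", "Duodenum", "T1", "T2")))
  merged <- mhcatlas:::apply_tissue_merge(
    mat, list("Small intestine" = c("Jejunum", "Duodenum")))
  expect_equal(unname(merged[1, "Small intestine"]), 20)
  expect_false("Jejunum" %in% colnames(merged))
})

test_that("permutation calibration is deterministic and near the analytic null", {
  null <- generate_null_screen(400, 10, seed = 3)
  cal1 <- calibrate_fp(null$protein, null$counts, n_permutations = 100,
                       seed = 11)
  cal2 <- calibrate_fp(null$protein, null$counts, n_permutations = 100,
                       seed = 11)
  expect_identical(cal1$fp_fraction_r2, cal2$fp_fraction_r2)
  analytic <- stats::pbeta(0.4, 0.5, 4, lower.tail = FALSE)
  se <- sqrt(analytic * (1 - analytic) / cal1$n_fits)
  expect_lt(abs(cal1$fp_fraction_r2 - analytic), 5 * se)
  expect_error(calibrate_fp(null$protein, null$counts, n_permutations = 10),
               "100 permutations")
})

test_that("null false-positive fraction decreases with tissue count", {
  fracs <- vapply(c(10, 15, 20), function(nt) {
    null <- generate_null_screen(2000, nt, seed = 29)
    f <- fit_abundance_matrix(null$protein, null$counts,
                              min_pairs = min(10, nt))
    mean(f$r_squared > 0.4, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})
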