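test_that("duplicate observations aggregate to the maximum intensity", {
  obs <- dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "s1", "T1", intensity = 10),
    obs_rows("AAAAAAAAA", "s1", "T1", intensity = 30, rank = 0.2),
    obs_rows("CCCCCCCCC", "s1", "T2", intensity = 5))
  cat <- peptide_catalog(obs)
  expect_equal(nrow(cat$observations), 2)
  a <- cat$observations[cat$observations$sequence == "AAAAAAAAA", ]
  expect_equal(a$intensity, 30)
  expect_equal(a$rank_score, 0.2)
})

test_that("aggregation is idempotent", {
  obs <- dplyr::bind_rows(
    obs_rows("AAAAAAAAA", "s1", c("T1", "T2")),
    obs_rows("AAAAAAAAA", "s1", "T1", intensity = 500),
    obs_rows("CCCCCCCCC", "s2", "T2"))
  cat1 <- peptide_catalog(obs)
  cat2 <- peptide_catalog(cat1$observations)
  expect_identical(cat1$observations, cat2$observations)
})

test_that("catalog validation rejects bad sequences and intensities", {
  expect_error(peptide_catalog(obs_rows("AAAB1AAAA", "s1", "T1")),
               "amino-acid")
  expect_error(peptide_catalog(obs_rows("AAAAAAAAA", "s1", "T1",
                                        intensity = 0)),
               "intensity")
  seqs <- strrep(c("A", "C", "D", "E", "F", "G", "H"), 9)
  too_many <- dplyr::bind_rows(lapply(1:7, function(i) {
    obs_rows(seqs[i], "s1", "T1", allele = sprintf("AL%02d", i))
  }))
  expect_error(peptide_catalog(too_many, species = "human"), "6 class I")
})

test_that("peptide tables round-trip through TSV and normalize synonyms", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sequence\tsubject\ttissue\tallele\trank\tintensity\tsource_genes",
    "AAAAAAAAA\tD1\tMyelon\tAL01\t0.5\t100\tgeneA;geneB",
    "CCCCCCCCC\tD1\tLiver\tAL02\t1.5\t20\tgeneC"), path)
  cat <- read_peptide_table(path, "human")
  expect_setequal(cat$tissues, c("Spinal cord", "Liver"))
  expect_equal(cat$observations$source_genes[[1]], c("geneA", "geneB"))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(cat, out)
  cat2 <- read_peptide_table(out, "human")
  expect_equal(cat2$observations$intensity, cat$observations$intensity,
               tolerance = 1e-9)
  expect_identical(cat2$observations$sequence, cat$observations$sequence)
})

test_that("missing mandatory columns and empty files are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sequence\tsubject\ttissue\tallele\trank", path)
  expect_error(read_peptide_table(path, "mouse"), "intensity")
  writeLines("sequence\tsubject\ttissue\tallele\trank\tintensity", path)
  cat <- read_peptide_table(path, "mouse")
  expect_equal(nrow(cat$observations), 0)
  expect_length(cat$tissues, 0)
})

test_that("matrix reader maps missing tokens and enforces invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tT1\tT2\tT3",
               "geneA\t1\tNA\t3",
               "geneB\t4\t5\t6"), path)
  m <- read_matrix(path, "expression")
  expect_equal(sum(is.na(m)), 1)
  expect_equal(m["geneB", "T3"], 6)
  expect_equal(colnames(m), c("T1", "T2", "T3"))

  writeLines(c("gene_id\tT1", "geneA\t1", "geneA\t2"), path)
  expect_error(read_matrix(path, "expression"), "geneA")
  writeLines(c("gene_id\tT1", "geneA\t-1"), path)
  expect_error(read_matrix(path, "expression"), "negative")
})

test_that("matrices round-trip exactly enough", {
  m <- matrix(c(pi, exp(1), 0, 123456.789, NA, 1e-7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("T1", "T2", "T3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path, id_name = "gene_id")
  m2 <- read_matrix(path, "expression")
  expect_equal(m2[rownames(m), colnames(m)], m, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("bedGraph tracks follow the half-open convention", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t3\t0.5", path)
  track <- read_conservation(path)
  expect_equal(track_values(track, "chr1", 0, 3), rep(0.5, 3))
  expect_error(track_values(track, "chr1", 0, 4), "beyond")
  writeLines("chr1\t0\t3\t1.5", path)
  expect_error(read_conservation(path), "\\[0, 1\\]")
})

test_that("gene models read strand-aware with exon blocks", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste("chr1", 100, 400, "geneA", 0, "+", 100, 400, "0,0,0", 2,
          "50,100,", "0,200,", sep = "\t"),
    paste("chr1", 1000, 1300, "geneB", 0, "-", 1000, 1300, "0,0,0", 1,
          "300,", "0,", sep = "\t")), path)
  gm <- read_gene_models(path)
  expect_equal(gm$tss, c(100L, 1299L))
  expect_equal(gm$strand, c("+", "-"))
  expect_equal(gm$exons[[1]],
               cbind(start = c(100L, 300L), end = c(150L, 400L)))
})

test_that("overlapping exon blocks merge into their union with a warning", {
  ex <- cbind(start = c(0L, 10L, 40L), end = c(20L, 30L, 50L))
  expect_warning(merged <- mhcatlas:::merge_intervals(ex), "merged")
  expect_equal(merged, cbind(start = c(0L, 40L), end = c(30L, 50L)))
})

test_that("percent labels use half-up integer rounding, one decimal below 2%", {
  expect_equal(report_fraction(1881, 7665)$label, "25%")
  expect_equal(report_fraction(1, 1000)$label, "0.1%")
  expect_equal(report_fraction(15, 1000)$label, "1.5%")
  expect_equal(report_fraction(245, 1000)$label, "25%")
})
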