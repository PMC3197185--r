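psmFile <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("PSM tables parse with typed probabilities and strict validation", {
  tab <- makePsms(c("AAAGGK", "MMMR", "CCCGGK"))
  got <- readPsmTable(psmFile(tab))
  expect_identical(nrow(got), 3L)
  expect_type(got$peptide_prob, "double")

  bad <- tab; bad$peptide_prob[2] <- 1.2
  expect_error(readPsmTable(psmFile(bad)), "line 3")

  noCol <- tab[, setdiff(names(tab), "condition")]
  expect_error(readPsmTable(psmFile(noCol)), "condition")

  expect_identical(nrow(readPsmTable(psmFile(tab[0, ]))), 0L)
})

test_that("entries with identical observed peptide sets merge into one group", {
  db <- makeTestDb(c(e1 = "AAAGGKMMMR", e2 = "AAAGGKMMMR", e3 = "WWWCCCK"))
  idx <- buildPeptideIndex(db, missedMax = 0, lenMin = 3)
  psms <- makePsms(c("AAAGGK", "MMMR", "AAAGGK", "WWWCCCK", "AAAGGK"))
  se <- inferProteins(psms, idx)
  rd <- SummarizedExperiment::rowData(se)
  expect_identical(nrow(se), 2L)
  shared <- rd[grepl("e1", rd$entry_ids), ]
  expect_identical(shared$entry_ids, "e1;e2")
  expect_identical(shared$n_unique_peptides, 2L)
  # 4 PSMs carry peptides of the merged group
  expect_identical(as.integer(SummarizedExperiment::assay(se)[shared$group_id, ]), 4L)

  empty <- inferProteins(psms[0, ], idx)
  expect_identical(nrow(empty), 0L)
})

test_that("shared peptides count toward every containing group", {
  db <- makeTestDb(c(e1 = "AAAGGKMMMR", e2 = "CCCGGKMMMR"))
  idx <- buildPeptideIndex(db, missedMax = 0, lenMin = 3)
  psms <- makePsms(c("AAAGGK", "CCCGGK", "MMMR", "MMMR"))
  se <- inferProteins(psms, idx)
  expect_identical(nrow(se), 2L)
  expect_identical(unname(rowSums(SummarizedExperiment::assay(se))),
                   c(3, 3))
})

test_that("group inference is invariant under PSM permutation", {
  set.seed(51)
  g <- generateTranscriptome(10, proteinLenRange = c(30, 60),
                             utrLenRange = c(5, 30), seed = 52)
  at <- annotateHeaders(g$transcripts, generateAnnotations(g$truth, seed = 53))
  db <- suppressMessages(buildSearchDb(at))
  idx <- buildPeptideIndex(db)
  psms <- simulatePsms(db, g$truth, depth = 300, replicates = 1, seed = 54)
  se1 <- inferProteins(psms, idx)
  se2 <- inferProteins(psms[sample.int(nrow(psms)), ], idx)
  expect_identical(SummarizedExperiment::rowData(se1),
                   SummarizedExperiment::rowData(se2))
  expect_identical(SummarizedExperiment::assay(se1),
                   SummarizedExperiment::assay(se2))
})

test_that("acceptance thresholds drop weak groups in the stated order", {
  db <- makeTestDb(c(e1 = "AAAGGKMMMR", e2 = "WWWCCCKDDDR"))
  idx <- buildPeptideIndex(db, missedMax = 0, lenMin = 3)

  # one unique peptide only -> removed by the two-peptide rule
  one <- makePsms(c("AAAGGK", "AAAGGK"))
  expect_identical(nrow(filterIdentifications(one, idx)), 0L)

  # protein probability below 0.95 -> removed
  low <- makePsms(c("AAAGGK", "MMMR"), protein_prob = 0.94)
  expect_identical(nrow(filterIdentifications(low, idx)), 0L)
  expect_identical(nrow(filterIdentifications(
    makePsms(c("AAAGGK", "MMMR"), protein_prob = 0.95), idx)), 1L)

  # peptide-level pass runs first: the 2nd peptide at 0.4 leaves one
  two <- makePsms(c("AAAGGK", "MMMR"))
  two$peptide_prob <- c(0.99, 0.40)
  expect_identical(nrow(filterIdentifications(two, idx)), 0L)
})

test_that("filtering is monotone in all three thresholds", {
  set.seed(55)
  g <- generateTranscriptome(15, proteinLenRange = c(30, 60),
                             utrLenRange = c(5, 30),
                             presentFraction = 0.6, seed = 56)
  at <- annotateHeaders(g$transcripts, generateAnnotations(g$truth, seed = 57))
  db <- suppressMessages(buildSearchDb(at))
  idx <- buildPeptideIndex(db)
  psms <- simulatePsms(db, g$truth, depth = 800, replicates = 1,
                       decoyHitRate = 0.1, seed = 58)
  grid <- expand.grid(minPeptides = c(1L, 2L, 3L),
                      minProteinProb = c(0, 0.5, 0.95),
                      minPeptideProb = c(0, 0.5, 0.9))
  counts <- mapply(function(mp, mpp, mqp)
    nrow(filterIdentifications(psms, idx, mp, mpp, mqp)),
    grid$minPeptides, grid$minProteinProb, grid$minPeptideProb)
  for (i in seq_len(nrow(grid)))
    for (j in seq_len(nrow(grid)))
      if (all(unlist(grid[i, ]) <= unlist(grid[j, ])))
        expect_gte(counts[i], counts[j])
})

test_that("target-decoy FDR follows the decoys/targets estimator", {
  cats <- c(rep("target", 99), "decoy")
  expect_equal(estimateFdr(cats), 1 / 99)
  expect_equal(estimateFdr(rep("target", 10)), 0)
  expect_equal(estimateFdr(c(rep("target", 50), rep("decoy", 50))), 1)
  expect_equal(estimateFdr(character()), 0)
  expect_warning(fdr <- estimateFdr(rep("decoy", 3)), "FDR reported as 1")
  expect_equal(fdr, 1)
  # contaminants excluded from both counts
  expect_equal(estimateFdr(c(rep("target", 99), "decoy",
                             rep("contaminant", 20))), 1 / 99)
  # alternative combined estimator
  expect_equal(estimateFdr(c(rep("target", 99), "decoy"),
                           method = "combined"), 2 / 100)
})
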