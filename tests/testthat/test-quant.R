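quantFixture <- function(seed = 61, depth = 2000, n = 20,
                         foldChanges = c(2, 10), nDepleteOnly = 1) {
  g <- generateTranscriptome(n, proteinLenRange = c(60, 120),
                             utrLenRange = c(10, 60),
                             foldChanges = foldChanges,
                             nDepleteOnly = nDepleteOnly, seed = seed)
  at <- annotateHeaders(g$transcripts,
                        generateAnnotations(g$truth, seed = seed + 1))
  db <- suppressMessages(buildSearchDb(at))
  idx <- buildPeptideIndex(db)
  psms <- simulatePsms(db, g$truth, depth = depth, seed = seed + 2)
  se <- filterIdentifications(psms, idx)
  list(g = g, db = db, se = addProteinLengths(se, db))
}

test_that("group length is the longest member entry", {
  set.seed(60)
  db <- makeTestDb(c(e1 = randomProtein(120), e2 = randomProtein(98)))
  idx <- buildPeptideIndex(db, missedMax = 0, lenMin = 5)
  # force both entries into one row each via their own peptides
  p1 <- digest(as.character(sequences(db)[[1]]), 0, 5, 50)$peptide[1]
  p2 <- digest(as.character(sequences(db)[[2]]), 0, 5, 50)$peptide[1]
  se <- inferProteins(makePsms(c(p1, p2)), idx)
  se <- addProteinLengths(se, db)
  rd <- SummarizedExperiment::rowData(se)
  expect_setequal(rd$L, c(120, 98))

  # a synthetic merged group takes the max length
  seM <- se
  SummarizedExperiment::rowData(seM)$entry_ids[1] <- "e1;e2"
  seM <- addProteinLengths(seM, db)
  expect_identical(SummarizedExperiment::rowData(seM)$L[1], 120)

  SummarizedExperiment::rowData(seM)$entry_ids[1] <- "e1;ghost"
  expect_error(addProteinLengths(seM, db), "missing from database")
})

test_that("count normalization scales to the reference condition totals", {
  fx <- quantFixture()
  se <- normalizeCounts(fx$se, "deplete")
  raw <- SummarizedExperiment::assay(se, "SpC")
  nrm <- SummarizedExperiment::assay(se, "SpC_norm")
  cond <- SummarizedExperiment::colData(se)$condition
  ref <- mean(colSums(raw)[cond == "deplete"])
  expect_equal(unname(colSums(nrm)), rep(ref, ncol(se)))
  expect_error(normalizeCounts(fx$se, "starved"), "not present")

  zero <- fx$se
  SummarizedExperiment::assay(zero, "SpC")[, 1] <- 0L
  expect_error(normalizeCounts(zero, "deplete"), "zero total")
})

test_that("NSAF divides counts by length and sums to one", {
  expect_equal(nsaf(c(4, 6), c(100, 300)), c(2 / 3, 1 / 3))
  expect_equal(nsaf(5, 10), 1)
  expect_equal(nsaf(c(5, 0), c(10, 10)), c(1, 0))
  expect_error(nsaf(c(0, 0), c(10, 10)), "all spectral counts are zero")
  expect_error(nsaf(c(1, 2), c(10, 0)), "positive")

  set.seed(62)
  for (i in 1:25) {
    n <- sample(2:300, 1)
    spc <- rpois(n, 5); spc[1] <- spc[1] + 1
    len <- sample(50:500, n, replace = TRUE)
    v <- nsaf(spc, len)
    expect_lt(abs(sum(v) - 1), 1e-9)
    expect_equal(nsaf(7L * spc, len), v)   # scale invariance
  }
})

test_that("per-sample NSAF conservation holds through the pipeline container", {
  fx <- quantFixture()
  q <- computeNsaf(normalizeCounts(fx$se, "deplete"), "SpC_norm")
  sums <- colSums(SummarizedExperiment::assay(q, "NSAF"))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(SummarizedExperiment::rowData(q)$category == "target"))
})

test_that("fold changes return ratios or zero-side sentinels", {
  expect_equal(foldChange(0.4, 0.2)$fc, 2)
  expect_identical(foldChange(0.4, 0.2)$type, "ratio")
  for (x in c(0.01, 0.3, 0.9))
    expect_equal(foldChange(x, x)$fc, 1)
  s <- foldChange(0.02, 0, pseudoNsaf = 1e-4)
  expect_identical(s$type, "deplete_only")
  expect_equal(s$fc, 0.02 / 1e-4)
  expect_identical(foldChange(0, 0.3, pseudoNsaf = 1e-4)$type, "replete_only")
  expect_identical(foldChange(0, 0)$type, "absent")
})

test_that("one-way ANOVA matches hand-checked values and handles degeneracy", {
  # identical values everywhere: no between-group variance
  r0 <- anovaOneway(rep(3.3, 6), rep(c("a", "b"), each = 3))
  expect_identical(c(r0$F, r0$p), c(0, 1))
  # zero within-group variance with distinct means: perfect separation
  r1 <- anovaOneway(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_identical(r1$F, Inf)
  expect_identical(r1$p, 0)
  # hand-computed: SSB = 1.5, MSW = 1
  r2 <- anovaOneway(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(r2$F, 1.5)
  expect_error(anovaOneway(c(1, 2, 3), c("a", "a", "b")), "two replicates")
  expect_error(anovaOneway(c(1, 2), c("a", "a")), "two groups")
})

test_that("ANOVA agrees with the brute-force F formula on random data", {
  set.seed(63)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    sizes <- sample(2:6, k, replace = TRUE)
    vals <- rnorm(sum(sizes), mean = rep(runif(k, 0, 3), sizes))
    grp <- rep(letters[1:k], sizes)
    got <- anovaOneway(vals, grp)
    want <- oracleAnova(vals, grp)
    expect_lt(abs(got$F - want$F), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
  }
})

test_that("differential table recovers planted effects with inclusive alpha", {
  fx <- quantFixture(seed = 64, depth = 3000)
  q <- computeNsaf(normalizeCounts(fx$se, "deplete"), "SpC_norm")
  d <- differentialTable(q)

  # sentinels sort first; planted deplete-only protein appears as sentinel
  sentinels <- d$fc_type %in% c("deplete_only", "replete_only")
  expect_true(all(which(sentinels) <= sum(sentinels)))
  expect_gte(sum(d$fc_type == "deplete_only"), 1)

  # significance boundary is inclusive: alpha == p keeps the flag TRUE
  mid <- d[d$fc_type == "ratio" & d$p_value > 1e-6 & d$p_value < 1, ][1, ]
  dEq <- differentialTable(q, alpha = mid$p_value)
  expect_true(dEq$significant[dEq$group_id == mid$group_id])
  dLt <- differentialTable(q, alpha = mid$p_value * (1 - 1e-9))
  expect_false(dLt$significant[dLt$group_id == mid$group_id])

  # abundant flag marks groups above ten summed spectra
  expect_identical(d$abundant, d$total_SpC > 10)
})
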