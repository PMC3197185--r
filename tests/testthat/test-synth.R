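test_that("transcriptome generation is seed-deterministic and recoverable", {
  g1 <- generateTranscriptome(10, seed = 81)
  g2 <- generateTranscriptome(10, seed = 81)
  expect_identical(as.character(g1$transcripts), as.character(g2$transcripts))
  expect_identical(g1$truth, g2$truth)
  g3 <- generateTranscriptome(10, seed = 82)
  expect_false(identical(as.character(g1$transcripts),
                         as.character(g3$transcripts)))

  # every ground-truth protein is recovered verbatim in its frame
  for (i in seq_len(10)) {
    segs <- sixFrameSegments(as.character(g1$transcripts[[i]]))
    expect_true(g1$truth$protein[i] %in%
                  segs$segment[segs$frame == g1$truth$cds_frame[i]])
  }
  expect_error(generateTranscriptome(0), ">= 1")
  expect_error(generateTranscriptome(5, proteinLenRange = c(50, 20)),
               "infeasible")
})

test_that("per-condition ground-truth abundances are normalized and planted", {
  g <- generateTranscriptome(50, foldChanges = c(2, 5, 10),
                             nDepleteOnly = 2, presentFraction = 0.8,
                             seed = 83)
  t <- g$truth
  expect_equal(sum(t$abund_replete), 1)
  expect_equal(sum(t$abund_deplete), 1)
  expect_true(all(t$abund_replete[!t$present] == 0))
  expect_identical(sum(is.infinite(t$planted_fold_change)), 2L)
  planted <- t[is.finite(t$planted_fold_change) & t$planted_fold_change != 1, ]
  # NSAF-scale ratio equals the planted value exactly by construction
  expect_equal(planted$abund_deplete / planted$abund_replete,
               planted$planted_fold_change)
})

test_that("annotation generation honours hit rate and plants duplicates", {
  g <- generateTranscriptome(30, proteinLenRange = c(30, 60),
                             utrLenRange = c(5, 30), seed = 84)
  all <- generateAnnotations(g$truth, hitRate = 1, seed = 85)
  at <- annotateHeaders(g$transcripts, all)
  expect_identical(sum(annotation(at)$annotated), 30L)
  # a planted duplicate pair surfaces as a "_2" suffix downstream
  expect_true(any(grepl("_2$", annotation(at)$header)))

  none <- generateAnnotations(g$truth, hitRate = 0, seed = 86)
  atN <- annotateHeaders(g$transcripts, none)
  expect_identical(sum(annotation(atN)$annotated), 0L)
})

test_that("simulated counts follow abundance x length multinomial weights", {
  truth <- data.frame(protein_id = c("P1", "P2"),
                      transcript_id = c("t1", "t2"), cds_frame = 1L,
                      length_aa = c(200L, 200L), protein = "",
                      present = TRUE, abund_replete = c(0.8, 0.2),
                      abund_deplete = c(0.8, 0.2),
                      planted_fold_change = 1,
                      stringsAsFactors = FALSE)
  sim <- simulateCounts(truth, depth = 5000, replicates = 1, seed = 87)
  n1 <- sim$counts["P1", "replete_1"]
  # binomial 99% interval around 0.8 of 5000
  expect_true(abs(n1 - 4000) < 2.58 * sqrt(5000 * 0.8 * 0.2) + 1)
  sim2 <- simulateCounts(truth, depth = 5000, replicates = 1, seed = 87)
  expect_identical(sim$counts, sim2$counts)
})

test_that("PSM simulation is seeded and plants decoys only when asked", {
  g <- generateTranscriptome(8, proteinLenRange = c(40, 80),
                             utrLenRange = c(5, 30), seed = 88)
  at <- annotateHeaders(g$transcripts, generateAnnotations(g$truth, seed = 89))
  db <- suppressMessages(buildSearchDb(at))
  p0 <- simulatePsms(db, g$truth, depth = 400, seed = 90)
  expect_identical(sum(p0$truth_class != "correct"), 0L)
  p0b <- simulatePsms(db, g$truth, depth = 400, seed = 90)
  expect_identical(p0, p0b)
  expect_error(simulatePsms(db, g$truth, depth = 400, decoyHitRate = 0.1,
                            falseTargetRate = 0.1, seed = 91),
               "absent proteins")
  # with only decoy planting, decoy PSMs appear at roughly the asked rate
  pD <- simulatePsms(db, g$truth, depth = 1000, decoyHitRate = 0.1,
                     falseTargetRate = 0, seed = 92)
  frac <- mean(pD$truth_class == "decoy")
  expect_true(abs(frac - 0.1) < 0.03)
})

test_that("pipeline runs rank planted fold changes correctly across seeds", {
  nSeeds <- 20
  ok <- logical(nSeeds)
  for (s in seq_len(nSeeds)) {
    g <- generateTranscriptome(50, proteinLenRange = c(60, 120),
                               utrLenRange = c(10, 60),
                               foldChanges = c(1, 2, 10), nDepleteOnly = 1,
                               seed = 500 + s)
    at <- annotateHeaders(g$transcripts,
                          generateAnnotations(g$truth, hitRate = 1,
                                              seed = 600 + s))
    db <- suppressMessages(buildSearchDb(at))
    idx <- buildPeptideIndex(db)
    psms <- simulatePsms(db, g$truth, depth = 2500, seed = 700 + s)
    se <- addProteinLengths(filterIdentifications(psms, idx), db)
    q <- computeNsaf(normalizeCounts(se, "deplete"), "SpC_norm")
    d <- differentialTable(q)

    # locate planted groups via their source transcripts
    m <- entryMeta(db)
    grpOf <- function(tx) {
      eids <- m$entry_id[!is.na(m$source_transcript) &
                           m$source_transcript == tx &
                           m$category == "target"]
      rd <- SummarizedExperiment::rowData(q)
      hit <- vapply(strsplit(rd$entry_ids, ";"), function(x)
        any(x %in% eids), logical(1))
      rd$group_id[hit][1]
    }
    t <- g$truth
    fc <- function(val) {
      tx <- t$transcript_id[t$planted & t$planted_fold_change == val][1]
      d$fold_change[d$group_id == grpOf(tx)]
    }
    gidDO <- grpOf(t$transcript_id[is.infinite(t$planted_fold_change)][1])
    ok[s] <- isTRUE(fc(10) > fc(2) && fc(2) > fc(1)) &&
      d$fc_type[d$group_id == gidDO] == "deplete_only"
  }
  expect_gte(mean(ok), 0.95)
})
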