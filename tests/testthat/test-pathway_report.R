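test_that("the packaged pathway roster loads and validates", {
  enz <- loadPathwayConfig()
  expect_true("DGAT" %in% enz$abbrev)
  expect_identical(enz$pathway[enz$abbrev == "DGAT"], "TAG")
  expect_identical(enz$pathway[enz$abbrev == "KAS"], "fatty_acid")
  expect_identical(enz$pathway[enz$abbrev == "AMPK"], "regulatory")
  expect_false(anyDuplicated(enz$abbrev) > 0)

  dup <- tempfile(fileext = ".yaml")
  writeLines(c("enzymes:",
               "  - {abbrev: KAS, full_name: a, pathway: fatty_acid, keywords: [x]}",
               "  - {abbrev: KAS, full_name: b, pathway: fatty_acid, keywords: [y]}"),
             dup)
  expect_error(loadPathwayConfig(dup), "duplicate")

  empty <- tempfile(fileext = ".yaml")
  writeLines("enzymes: []", empty)
  expect_error(loadPathwayConfig(empty), "no enzymes")

  noKw <- tempfile(fileext = ".yaml")
  writeLines(c("enzymes:",
               "  - {abbrev: KAS, full_name: a, pathway: fatty_acid}"), noKw)
  expect_error(loadPathwayConfig(noKw), "without keywords")
})

test_that("enzyme matching is case-insensitive, longest keyword wins, injective", {
  enz <- loadPathwayConfig()
  headers <- c(
    G1 = "ref|X1| Diacylglycerol Acyltransferase type 2",
    G2 = "ref|X2| 3-ketoacyl-ACP reductase, chloroplastic",
    G3 = "ref|X3| completely unrelated hypothetical protein",
    G4 = "ref|X4| diacylglycerol kinase isoform 1")
  m <- matchEnzymes(headers, enz)
  expect_identical(m$DGAT, "G1")
  expect_identical(m$KAR, "G2")
  expect_identical(m$DAGK, "G4")
  expect_identical(length(m$ACCase), 0L)
  # every group lands in at most one enzyme row
  all_assigned <- unlist(m, use.names = FALSE)
  expect_false(anyDuplicated(all_assigned) > 0)
  expect_false("G3" %in% all_assigned)
  expect_setequal(names(m), enz$abbrev)
})

test_that("pathway rows scale NSAF by 1e5 and render sentinels", {
  enz <- loadPathwayConfig()
  diff <- data.frame(
    group_id = c("G1", "G2"),
    nsaf_mean_replete = c(2e-5, 0),
    nsaf_mean_deplete = c(4e-5, 3e-5),
    fc_type = c("ratio", "deplete_only"),
    fold_change = c(2, 120.3), F = c(10, 99),
    p_value = c(0.01, 0.001), significant = c(TRUE, TRUE),
    total_SpC = c(50, 20), abundant = c(TRUE, TRUE),
    stringsAsFactors = FALSE)
  emap <- matchEnzymes(c(G1 = "acetyl-CoA carboxylase",
                         G2 = "diacylglycerol acyltransferase"), enz)
  tab <- pathwayTable(diff, emap, enz)
  acc <- tab[tab$abbrev == "ACCase", ]
  expect_equal(acc$nsaf_replete_1e5, 2)
  expect_equal(acc$nsaf_deplete_1e5, 4)
  expect_identical(acc$fc_display, "2.0")
  dgat <- tab[tab$abbrev == "DGAT", ]
  expect_identical(dgat$fc_display, ">120.3")
  expect_identical(tab$status[tab$abbrev == "KAS"], "not identified")
  expect_identical(nrow(tab), nrow(enz))
  txt <- formatPathwayReport(tab)
  expect_identical(length(txt), nrow(enz) + 1L)
})

test_that("the full pipeline produces all outputs and reruns identically", {
  g <- generateTranscriptome(40, proteinLenRange = c(60, 120),
                             utrLenRange = c(10, 60),
                             foldChanges = c(2, 10), nDepleteOnly = 1,
                             seed = 71)
  # the deplete-only protein plays DGAT, mirroring its >100-fold reporting
  enzTx <- g$truth$transcript_id[is.infinite(g$truth$planted_fold_change)][1]
  titles <- setNames("diacylglycerol acyltransferase", enzTx)
  hits <- generateAnnotations(g$truth, hitRate = 1, titles = titles,
                              seed = 72)
  psms <- simulatePsms(suppressMessages(buildSearchDb(
    annotateHeaders(g$transcripts, hits))), g$truth,
    depth = 1500, seed = 73)
  txF <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(g$transcripts, txF)
  blastF <- tempfile(fileext = ".tsv"); writeBlastTab(hits, blastF)
  psmF <- tempfile(fileext = ".tsv"); writePsmTable(psms, psmF)

  out1 <- tempfile(); out2 <- tempfile()
  res <- suppressWarnings(runPipeline(txF, blastF, psmF, outDir = out1))
  expected <- c("annotated.fasta", "searchdb.fasta", "filtered_ids.tsv",
                "quant.tsv", "differential.tsv", "pathway_report.tsv",
                "manifest.json")
  expect_true(all(file.exists(file.path(out1, expected))))

  # the planted DGAT transcript reaches the pathway report
  pw <- res$pathway
  expect_identical(pw$status[pw$abbrev == "DGAT"], "identified")

  # rerun: identical outputs, manifest differs only by timestamp
  suppressWarnings(runPipeline(txF, blastF, psmF, outDir = out2))
  for (f in setdiff(expected, "manifest.json"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  m1$generated <- m2$generated <- NULL
  expect_identical(m1, m2)

  # a missing PSM file aborts naming the filtering stage
  expect_error(runPipeline(txF, blastF, "/nonexistent/psms.tsv",
                           outDir = tempfile()),
               "ident_filter")
})
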