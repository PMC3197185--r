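## End-to-end orchestration: annotation -> search database -> filtering ->
## NSAF quantification -> pathway report, with a run manifest.

#' Run the full transcriptome-to-pathway pipeline
#'
#' Executes, in order: best-hit annotation and header deduplication,
#' six-frame search-database construction with reversed decoys (and
#' contaminants when given), peptide indexing, PSM filtering to the
#' two-peptide/probability thresholds with target-decoy FDR estimation,
#' NSAF quantification with differential statistics, and the pathway
#' abundance report. All outputs are written under `outDir`, together
#' with a `manifest.json` recording package version, parameters and
#' per-stage record counts. Reruns on identical inputs are byte-identical
#' for every deterministic stage. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param transcripts Path to the transcript FASTA, or a `DNAStringSet`.
#' @param blast Path to the BLAST tabular results, or a hit `data.frame`.
#' @param psms Path(s) to PSM TSV file(s), or a PSM `data.frame`.
#' @param contaminants Optional contaminant FASTA path or `AAStringSet`.
#' @param outDir Output directory (created if absent).
#' @param pathwayConfig Pathway YAML path (default the packaged roster).
#' @param maxEvalue Best-hit qualifying threshold (default 1e-3).
#' @param minSegLen Minimum six-frame segment length, aa (default 7).
#' @param missedMax,lenMin,lenMax Digestion parameters (defaults 2, 6,
#'   50).
#' @param minPeptides,minProteinProb,minPeptideProb Acceptance thresholds
#'   (defaults 2, 0.95, 0.50).
#' @param referenceCondition Condition whose total spectral counts define
#'   the normalization scale (default `"deplete"`).
#' @param conditionDeplete,conditionReplete Condition labels for the
#'   differential contrast.
#' @param alpha Significance level (default 0.05).
#' @return Invisibly, a list with the intermediate objects:
#'   `annotated`, `db`, `index`, `filtered`, `fdr`, `quant`, `diff`,
#'   `pathway`, `manifest`.
#' @export
runPipeline <- function(transcripts, blast, psms, contaminants = NULL,
                        outDir, pathwayConfig = NULL, maxEvalue = 1e-3,
                        minSegLen = 7L, missedMax = 2L, lenMin = 6L,
                        lenMax = 50L, minPeptides = 2L,
                        minProteinProb = 0.95, minPeptideProb = 0.50,
                        referenceCondition = "deplete",
                        conditionDeplete = "deplete",
                        conditionReplete = "replete", alpha = 0.05) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  tx <- stage("annotation", {
    if (is.character(transcripts)) {
      if (!file.exists(transcripts))
        stop("transcript FASTA not found: ", transcripts)
      readDNAStringSet(transcripts)
    } else transcripts
  })
  hits <- stage("annotation", {
    if (is.data.frame(blast)) blast else readBlastTab(blast)
  })
  annotated <- stage("annotation", annotateHeaders(tx, hits, maxEvalue))
  stage("annotation",
        writeAnnotatedFasta(annotated, file.path(outDir, "annotated.fasta")))

  db <- stage("search_db",
              suppressMessages(buildSearchDb(annotated, minLen = minSegLen,
                                             contaminants = contaminants)))
  stage("search_db", writeSearchDb(db, file.path(outDir, "searchdb.fasta")))

  index <- stage("peptide_map",
                 buildPeptideIndex(db, missedMax, lenMin, lenMax))

  psmTab <- stage("ident_filter", {
    if (is.data.frame(psms)) psms
    else {
      missing <- psms[!file.exists(psms)]
      if (length(missing)) stop("PSM file not found: ", missing[1L])
      do.call(rbind, lapply(psms, readPsmTable))
    }
  })
  filtered <- stage("ident_filter",
                    filterIdentifications(psmTab, index, minPeptides,
                                          minProteinProb, minPeptideProb))
  fdr <- stage("ident_filter", estimateFdr(filtered))
  stage("ident_filter",
        writeIdentificationTable(filtered,
                                 file.path(outDir, "filtered_ids.tsv")))

  quant <- stage("quant", {
    q <- addProteinLengths(filtered, db)
    q <- normalizeCounts(q, referenceCondition)
    computeNsaf(q, assayName = "SpC_norm")
  })
  stage("quant", {
    long <- do.call(rbind, lapply(colnames(quant), function(s)
      data.frame(group_id = rowData(quant)$group_id, sample = s,
                 condition = colData(quant)[s, "condition"],
                 replicate = colData(quant)[s, "replicate"],
                 SpC = assay(quant, "SpC")[, s],
                 L = rowData(quant)$L,
                 NSAF = assay(quant, "NSAF")[, s],
                 stringsAsFactors = FALSE)))
    write.table(long, file.path(outDir, "quant.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  diff <- stage("quant",
                differentialTable(quant, conditionDeplete,
                                  conditionReplete, alpha = alpha))
  stage("quant",
        write.table(diff, file.path(outDir, "differential.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE))

  pw <- stage("pathway_report", {
    enzymes <- if (is.null(pathwayConfig)) loadPathwayConfig()
               else loadPathwayConfig(pathwayConfig)
    headers <- setNames(
      vapply(strsplit(rowData(quant)$entry_ids, ";", fixed = TRUE),
             function(ids) paste(
               unique(entryMeta(db)$header[match(ids,
                                                 entryMeta(db)$entry_id)]),
               collapse = " / "), character(1)),
      rowData(quant)$group_id)
    emap <- matchEnzymes(headers, enzymes)
    tab <- pathwayTable(diff, emap, enzymes)
    write.table(tab[, setdiff(colnames(tab), "keywords")],
                file.path(outDir, "pathway_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(formatPathwayReport(tab),
               file.path(outDir, "pathway_report.txt"))
    tab
  })

  manifest <- list(
    package = "TransProteo",
    version = as.character(packageVersion("TransProteo")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(maxEvalue = maxEvalue, minSegLen = minSegLen,
                      missedMax = missedMax, lenMin = lenMin,
                      lenMax = lenMax, minPeptides = minPeptides,
                      minProteinProb = minProteinProb,
                      minPeptideProb = minPeptideProb,
                      referenceCondition = referenceCondition,
                      alpha = alpha),
    counts = list(
      transcripts = length(annotated),
      annotated = sum(annotation(annotated)$annotated),
      db_entries = length(db),
      db_targets = sum(entryMeta(db)$category == "target"),
      db_decoys = sum(entryMeta(db)$category == "decoy"),
      db_contaminants = sum(entryMeta(db)$category == "contaminant"),
      psms = nrow(psmTab),
      filtered_groups = nrow(filtered),
      quantified_groups = nrow(quant),
      estimated_fdr = fdr))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(annotated = annotated, db = db, index = index,
                 filtered = filtered, fdr = fdr, quant = quant,
                 diff = diff, pathway = pw, manifest = manifest))
}
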