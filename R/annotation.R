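## BLAST tabular parsing, best-hit selection under the E-value rule, header
## transfer onto transcripts and header deduplication.

.BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                  "align_length", "mismatches", "gap_opens", "q_start",
                  "q_end", "s_start", "s_end", "evalue", "bitscore")

#' Read tabular BLAST results (outfmt 6)
#'
#' Parses the canonical 12-column tab-separated BLAST output, with an
#' optional 13th column holding the subject title. Comment lines starting
#' with `#` are skipped. A line with fewer than 12 fields, or an E-value or
#' bitscore that does not parse as a number, is rejected with its line
#' number.
#'
#' @param file Path to a TSV file, or a character vector of lines (any
#'   element containing a tab is taken as data, so a multi-line string also
#'   works).
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `percent_identity`, `evalue`, `bitscore`, `subject_title` (empty
#'   string when the input has no title column).
#' @export
readBlastTab <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\t", file) && file.exists(file))
    readLines(file) else file
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), evalue = numeric(),
                      bitscore = numeric(), subject_title = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop(sprintf("line %d: expected >= 12 tab-separated fields, found %d",
                 lineNo[which(nf < 12L)[1L]], nf[which(nf < 12L)[1L]]))
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  ev <- suppressWarnings(as.numeric(getcol(11L)))
  if (anyNA(ev))
    stop(sprintf("line %d: unparseable E-value '%s'",
                 lineNo[which(is.na(ev))[1L]],
                 getcol(11L)[which(is.na(ev))[1L]]))
  bs <- suppressWarnings(as.numeric(getcol(12L)))
  if (anyNA(bs))
    stop(sprintf("line %d: unparseable bitscore '%s'",
                 lineNo[which(is.na(bs))[1L]],
                 getcol(12L)[which(is.na(bs))[1L]]))
  if (any(ev < 0))
    stop(sprintf("line %d: negative E-value", lineNo[which(ev < 0)[1L]]))
  title <- ifelse(nf >= 13L,
                  vapply(fields, function(f)
                    if (length(f) >= 13L) f[[13L]] else "", character(1)),
                  "")
  data.frame(query_id = getcol(1L), subject_id = getcol(2L),
             percent_identity = suppressWarnings(as.numeric(getcol(3L))),
             evalue = ev, bitscore = bs, subject_title = title,
             stringsAsFactors = FALSE)
}

#' Best BLAST hit for one query under the E-value rule
#'
#' Returns the hit with the smallest E-value strictly below `maxEvalue`
#' (default `1e-3`). Ties on E-value are broken by the higher bitscore,
#' then by the lexicographically smallest subject id, so the selection is
#' independent of input order.
#'
#' @param hits `data.frame` of hits for a single query (as from
#'   [readBlastTab()]).
#' @param maxEvalue Qualifying threshold; hits must have `evalue <
#'   maxEvalue`.
#' @return One-row `data.frame`, or `NULL` when no hit qualifies.
#' @export
bestHit <- function(hits, maxEvalue = 1e-3) {
  if (nrow(hits) == 0L) return(NULL)
  if (length(unique(hits$query_id)) > 1L)
    stop("bestHit() expects hits for a single query_id; got ",
         length(unique(hits$query_id)))
  hits <- hits[hits$evalue < maxEvalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  o <- order(hits$evalue, -hits$bitscore, hits$subject_id)
  hits[o[1L], , drop = FALSE]
}

#' Best hit per query over a whole hit table
#'
#' Applies [bestHit()] to every query in a BLAST tabular result.
#'
#' @inheritParams bestHit
#' @return `data.frame` with one row per query that has a qualifying hit.
#' @export
bestHits <- function(hits, maxEvalue = 1e-3) {
  if (nrow(hits) == 0L) return(hits)
  parts <- split(hits, hits$query_id)
  res <- lapply(parts, bestHit, maxEvalue = maxEvalue)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(hits[0L, , drop = FALSE])
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## first occurrence verbatim, k-th duplicate suffixed "_k" (k from 2)
.dedupHeaders <- function(headers) {
  if (!length(headers)) return(character())
  counts <- new.env(parent = emptyenv())
  vapply(headers, function(h) {
    k <- (get0(h, envir = counts, ifnotfound = 0L)) + 1L
    assign(h, k, envir = counts)
    if (k == 1L) h else paste0(h, "_", k)
  }, character(1), USE.NAMES = FALSE)
}

#' Transfer best-hit headers onto transcripts
#'
#' Annotated transcripts take the header of their best BLAST hit
#' (`subject_id`, plus the subject title when the tabular input carried
#' one); transcripts without a qualifying hit keep their assembly id as
#' header and are retained (set `annotatedOnly = TRUE` downstream to
#' restrict the database to annotated transcripts). Duplicate headers are
#' made unique by appending ascending numbers: the first occurrence is kept
#' verbatim, the k-th duplicate gets suffix `_k` starting at `_2`.
#'
#' @param transcripts Named [Biostrings::DNAStringSet] of assembled
#'   transcripts (unique, non-empty names).
#' @param hits BLAST tabular `data.frame` from [readBlastTab()], or an
#'   already-reduced best-hit table.
#' @param maxEvalue Qualifying E-value threshold (default `1e-3`).
#' @return An [AnnotatedTranscriptome-class] object.
#' @export
annotateHeaders <- function(transcripts, hits, maxEvalue = 1e-3) {
  if (length(transcripts) &&
      (is.null(names(transcripts)) || any(!nzchar(names(transcripts)))))
    stop("transcripts must be named by assembly id")
  if (anyDuplicated(names(transcripts)))
    stop("transcript ids must be unique within an assembly")
  ids <- names(transcripts)
  if (is.null(ids)) ids <- character(0)
  bh <- bestHits(hits, maxEvalue = maxEvalue)
  idx <- match(ids, bh$query_id)
  hit <- !is.na(idx)
  raw <- ifelse(hit,
                ifelse(nzchar(bh$subject_title[idx]) & !is.na(bh$subject_title[idx]),
                       paste(bh$subject_id[idx], bh$subject_title[idx]),
                       bh$subject_id[idx]),
                ids)
  final <- .dedupHeaders(raw)
  anno <- DataFrame(transcript_id = ids, header = final, raw_header = raw,
                    annotated = hit,
                    subject_id = ifelse(hit, bh$subject_id[idx], NA_character_),
                    evalue = ifelse(hit, bh$evalue[idx], NA_real_),
                    bitscore = ifelse(hit, bh$bitscore[idx], NA_real_))
  new("AnnotatedTranscriptome", transcripts = transcripts, anno = anno)
}

#' Annotation summary counts and percentages
#'
#' Counts annotated transcripts and zero-E-value hits, and reports
#' percentages rounded to one decimal: the annotation rate over all
#' transcripts and the zero-E-value share over annotated transcripts.
#'
#' @param x An [AnnotatedTranscriptome-class], or a list/data.frame with
#'   fields `annotated` (logical) and `evalue` (numeric, NA when
#'   unannotated).
#' @return Named list: `n_total`, `n_annotated`, `n_evalue_zero`,
#'   `percent_annotated`, `percent_evalue_zero`.
#' @export
annotationSummary <- function(x) {
  a <- if (is(x, "AnnotatedTranscriptome")) annotation(x) else x
  nTotal <- length(a$annotated)
  nAnn <- sum(a$annotated)
  nZero <- sum(a$annotated & !is.na(a$evalue) & a$evalue == 0)
  list(n_total = nTotal,
       n_annotated = nAnn,
       n_evalue_zero = nZero,
       percent_annotated = if (nTotal) round(100 * nAnn / nTotal, 1) else 0,
       percent_evalue_zero = if (nAnn) round(100 * nZero / nAnn, 1) else 0)
}

#' Percentage of a count over a denominator, as printed in reports
#'
#' Small reporting helper used by the summary functions: `100 * n / d`
#' rounded to `digits` decimals; 0 when the denominator is 0.
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @param digits Decimals to keep (default 1).
#' @return Numeric percentage.
#' @export
percentOf <- function(n, d, digits = 1) {
  if (d == 0) return(0)
  round(100 * n / d, digits)
}

#' Write annotated transcripts as FASTA
#'
#' Writes the transcript sequences under their final (deduplicated)
#' headers, 60 columns wide, together with a TSV sidecar mapping original
#' transcript ids to final headers with the best-hit statistics.
#'
#' @param x An [AnnotatedTranscriptome-class].
#' @param file Output FASTA path.
#' @param mapFile Optional sidecar TSV path (default `paste0(file,
#'   ".map.tsv")`; `NULL` suppresses it).
#' @return Invisibly, `file`.
#' @export
writeAnnotatedFasta <- function(x, file,
                                mapFile = paste0(file, ".map.tsv")) {
  seqs <- sequences(x)
  names(seqs) <- annotation(x)$header
  writeXStringSet(seqs, file, width = 60L)
  if (!is.null(mapFile)) {
    a <- as.data.frame(annotation(x))
    write.table(a[, c("transcript_id", "header", "evalue", "bitscore")],
                mapFile, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
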