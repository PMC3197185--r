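#' @title Core S4 containers
#' @description S4 classes holding the annotated transcriptome, the protein
#'   search database and the tryptic peptide index.
#' @name TransProteo-classes
NULL

setClassUnion("DataFrameOrNULL", c("DataFrame", "NULL"))

#' AnnotatedTranscriptome: transcripts with transferred BLAST headers
#'
#' Couples a [Biostrings::DNAStringSet] of assembled transcripts with a
#' per-transcript annotation table produced by [annotateHeaders()]. The
#' `anno` table carries one row per transcript, in the same order as the
#' sequences, with the deduplicated final header, the annotation flag and
#' the best-hit statistics.
#'
#' @slot transcripts A `DNAStringSet`, names are assembly transcript ids.
#' @slot anno A `DataFrame` with columns `transcript_id`, `header`
#'   (deduplicated final header), `raw_header` (header before
#'   deduplication), `annotated` (logical), `subject_id`, `evalue`,
#'   `bitscore` (NA for unannotated transcripts).
#'
#' @exportClass AnnotatedTranscriptome
setClass("AnnotatedTranscriptome",
  slots = c(transcripts = "DNAStringSet", anno = "DataFrame"))

setValidity("AnnotatedTranscriptome", function(object) {
  msg <- character()
  a <- object@anno
  need <- c("transcript_id", "header", "raw_header", "annotated",
            "subject_id", "evalue", "bitscore")
  if (!all(need %in% colnames(a)))
    msg <- c(msg, paste("anno must have columns:",
                        paste(setdiff(need, colnames(a)), collapse = ", ")))
  else {
    if (length(object@transcripts) != nrow(a))
      msg <- c(msg, "one anno row per transcript required")
    if (anyDuplicated(a$header))
      msg <- c(msg, "final headers must be unique after deduplication")
    if (nrow(a) && !identical(names(object@transcripts), a$transcript_id))
      msg <- c(msg, "anno rows must follow transcript order")
    bad <- a$annotated & is.na(a$evalue)
    if (any(bad))
      msg <- c(msg, "annotated transcripts must carry a best-hit evalue")
  }
  if (length(msg)) msg else TRUE
})

#' ProteinDb: a categorized protein search database
#'
#' An amino-acid sequence set with per-entry metadata: entry identifier,
#' display header, category (`target`, `decoy`, `contaminant`), and for
#' target entries the source transcript, reading frame and segment number.
#' Decoy entries are whole-sequence reversals with the `REV_` identifier
#' prefix; contaminants carry the `CONT_` prefix.
#'
#' @slot aa An `AAStringSet`, names are entry ids.
#' @slot meta A `DataFrame` with columns `entry_id`, `header`, `category`,
#'   `source_transcript`, `frame`, `seg` (NA where not applicable).
#'
#' @exportClass ProteinDb
setClass("ProteinDb", slots = c(aa = "AAStringSet", meta = "DataFrame"))

setValidity("ProteinDb", function(object) {
  msg <- character()
  m <- object@meta
  need <- c("entry_id", "header", "category", "source_transcript",
            "frame", "seg")
  if (!all(need %in% colnames(m)))
    return(paste("meta must have columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (length(object@aa) != nrow(m))
    msg <- c(msg, "one meta row per sequence required")
  if (nrow(m)) {
    if (!identical(names(object@aa), m$entry_id))
      msg <- c(msg, "sequence names must equal meta$entry_id")
    if (anyDuplicated(m$entry_id))
      msg <- c(msg, "entry ids must be unique")
    if (!all(m$category %in% c("target", "decoy", "contaminant")))
      msg <- c(msg, "category must be target, decoy or contaminant")
    isDecoy <- m$category == "decoy"
    if (any(isDecoy & !startsWith(m$entry_id, "REV_")))
      msg <- c(msg, "decoy entry ids must be prefixed 'REV_'")
    if (any(!isDecoy & startsWith(m$entry_id, "REV_")))
      msg <- c(msg, "'REV_' prefix is reserved for decoys")
    w <- width(object@aa)
    if (any(w == 0L))
      msg <- c(msg, "entries must have non-empty sequences")
    seqs <- as.character(object@aa)
    if (any(grepl("*", seqs, fixed = TRUE)))
      msg <- c(msg, "entries must not contain stop symbols '*'")
    tgt <- m$category == "target"
    if (any(tgt & (is.na(m$source_transcript) | is.na(m$frame))))
      msg <- c(msg, "target entries must carry source_transcript and frame")
  }
  if (length(msg)) msg else TRUE
})

#' PeptideIndex: exact-match tryptic peptide lookup
#'
#' Maps every in-silico tryptic peptide of a [ProteinDb] to the set of
#' entries that produce it, under fixed digestion parameters. Built by
#' [buildPeptideIndex()]; queried with [mapPeptides()].
#'
#' @slot env An environment keyed by peptide sequence; each value is a
#'   character vector of entry ids.
#' @slot params Named list of the digestion parameters the index was built
#'   with (`missedMax`, `lenMin`, `lenMax`, `collapseIL`).
#'
#' @exportClass PeptideIndex
setClass("PeptideIndex",
  slots = c(env = "environment", params = "list"))

## ---- accessors ----

#' @describeIn TransProteo-classes Number of entries / transcripts.
#' @param x An object.
#' @export
setMethod("length", "ProteinDb", function(x) length(x@aa))

#' @describeIn TransProteo-classes Number of transcripts.
#' @export
setMethod("length", "AnnotatedTranscriptome", function(x) length(x@transcripts))

#' Accessors for TransProteo containers
#'
#' `sequences()` returns the underlying `XStringSet`; `entryMeta()` the
#' per-entry metadata of a [ProteinDb]; `annotation()` the per-transcript
#' annotation table; `entryCategory()` the target/decoy/contaminant label.
#'
#' @param x A `ProteinDb` or `AnnotatedTranscriptome`.
#' @return See individual generics.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setMethod("sequences", "ProteinDb", function(x) x@aa)

#' @rdname accessors
#' @export
setMethod("sequences", "AnnotatedTranscriptome", function(x) x@transcripts)

#' @rdname accessors
#' @export
setGeneric("entryMeta", function(x) standardGeneric("entryMeta"))

#' @rdname accessors
#' @export
setMethod("entryMeta", "ProteinDb", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("entryCategory", function(x) standardGeneric("entryCategory"))

#' @rdname accessors
#' @export
setMethod("entryCategory", "ProteinDb",
          function(x) setNames(x@meta$category, x@meta$entry_id))

#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))

#' @rdname accessors
#' @export
setMethod("annotation", "AnnotatedTranscriptome", function(x) x@anno)

setMethod("show", "AnnotatedTranscriptome", function(object) {
  n <- length(object)
  na <- sum(object@anno$annotated)
  cat("AnnotatedTranscriptome with", n, "transcripts (",
      na, "annotated )\n")
  if (n) {
    cat("  mean length:", round(mean(width(object@transcripts)), 1), "nt\n")
    cat("  headers:", paste(head(object@anno$header, 3), collapse = "; "),
        if (n > 3) "...\n" else "\n")
  }
})

setMethod("show", "ProteinDb", function(object) {
  tab <- table(factor(object@meta$category,
                      levels = c("target", "decoy", "contaminant")))
  cat("ProteinDb with", length(object), "entries",
      sprintf("(%d target, %d decoy, %d contaminant)\n",
              tab[["target"]], tab[["decoy"]], tab[["contaminant"]]))
})

setMethod("show", "PeptideIndex", function(object) {
  p <- object@params
  cat("PeptideIndex over", length(ls(object@env)), "distinct peptides",
      sprintf("(missed<=%d, length %d-%d%s)\n", p$missedMax, p$lenMin,
              p$lenMax, if (isTRUE(p$collapseIL)) ", I=L" else ""))
})
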