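## Assembly of the concatenated target + reversed-decoy + contaminant
## protein search database from annotated transcripts.

.newProteinDb <- function(aa, meta) {
  names(aa) <- meta$entry_id
  new("ProteinDb", aa = aa, meta = meta)
}

.emptyDbMeta <- function() {
  DataFrame(entry_id = character(), header = character(),
            category = character(), source_transcript = character(),
            frame = integer(), seg = integer())
}

#' Build the target protein database by six-frame translation
#'
#' Translates every transcript in all six frames, splits at stop codons
#' and emits one target entry per stop-free segment of at least `minLen`
#' amino acids. Entry ids are `"<final_header>|frame=<f>|seg=<n>"` with
#' the transcript's deduplicated header, so they are unique. Entries are
#' ordered deterministically: transcript input order, then frames
#' +1, +2, +3, -1, -2, -3, then position.
#'
#' @param x An [AnnotatedTranscriptome-class] (headers already
#'   deduplicated).
#' @param minLen Minimum segment length in amino acids (default 7).
#' @param annotatedOnly If `TRUE`, only transcripts with a qualifying
#'   BLAST hit contribute entries (default `FALSE`: unannotated
#'   transcripts are retained under their assembly ids).
#' @return A [ProteinDb-class] of target entries.
#' @export
buildTargetDb <- function(x, minLen = 7L, annotatedOnly = FALSE) {
  a <- annotation(x)
  seqs <- as.character(sequences(x))
  keep <- if (annotatedOnly) which(a$annotated) else seq_along(seqs)
  res <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    segs <- sixFrameSegments(seqs[[i]], minLen = minLen)
    if (nrow(segs) == 0L) next
    fsign <- ifelse(segs$frame > 0, "+", "")
    res[[j]] <- data.frame(
      entry_id = sprintf("%s|frame=%s%d|seg=%d", a$header[i], fsign,
                         segs$frame, segs$seg),
      header = a$header[i],
      source_transcript = a$transcript_id[i],
      frame = segs$frame, seg = segs$seg, segment = segs$segment,
      stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(.newProteinDb(AAStringSet(), .emptyDbMeta()))
  tab <- do.call(rbind, res)
  meta <- DataFrame(entry_id = tab$entry_id, header = tab$header,
                    category = rep("target", nrow(tab)),
                    source_transcript = tab$source_transcript,
                    frame = tab$frame, seg = tab$seg)
  .newProteinDb(AAStringSet(tab$segment), meta)
}

#' Generate reversed decoy entries
#'
#' Produces one decoy per input entry by whole-sequence reversal, with the
#' `REV_` id prefix. Decoys are generated from targets and contaminants
#' alike, so FDR estimation treats contaminants as ordinary database
#' members. Re-decoying a decoy is rejected. Palindromic sequences whose
#' decoy equals the source are flagged with a message.
#'
#' @param db A [ProteinDb-class] of target and/or contaminant entries.
#' @return A [ProteinDb-class] holding only the decoy entries, in input
#'   order.
#' @export
makeDecoys <- function(db) {
  m <- entryMeta(db)
  if (any(m$category == "decoy"))
    stop("input already contains decoy entries; refusing to double-decoy")
  if (length(db) == 0L)
    return(.newProteinDb(AAStringSet(), .emptyDbMeta()))
  rev <- reverse(sequences(db))
  self <- as.character(rev) == as.character(sequences(db))
  if (any(self))
    message(sum(self), " palindromic entr",
            if (sum(self) == 1L) "y is" else "ies are",
            " self-identical under reversal: ",
            paste(head(m$entry_id[self], 5L), collapse = ", "))
  meta <- DataFrame(entry_id = paste0("REV_", m$entry_id),
                    header = paste0("REV_", m$header),
                    category = rep("decoy", nrow(m)),
                    source_transcript = m$source_transcript,
                    frame = m$frame, seg = m$seg)
  .newProteinDb(rev, meta)
}

#' Append contaminant proteins to a database
#'
#' Adds common background proteins (e.g. the cRAP set: keratins, trypsin)
#' to the search database so that peptides derived from them are not
#' falsely assigned to biological proteins. Contaminant ids receive the
#' `CONT_` prefix; a prefixed id colliding with an existing entry id is an
#' error. Run [makeDecoys()] after appending so contaminants are decoyed
#' too.
#'
#' @param db A [ProteinDb-class].
#' @param contaminants Path to a contaminant FASTA file, or an
#'   `AAStringSet`.
#' @return The database with contaminant entries appended.
#' @export
appendContaminants <- function(db, contaminants) {
  aa <- if (is(contaminants, "AAStringSet")) contaminants
        else readAAStringSet(contaminants)
  if (length(aa) == 0L) return(db)
  ids <- sub("\\s.*$", "", names(aa))
  ids <- ifelse(startsWith(ids, "CONT_"), ids, paste0("CONT_", ids))
  dup <- ids %in% entryMeta(db)$entry_id | duplicated(ids)
  if (any(dup))
    stop("contaminant header collides with an existing entry: ",
         ids[which(dup)[1L]])
  cmeta <- DataFrame(entry_id = ids, header = ids,
                     category = rep("contaminant", length(aa)),
                     source_transcript = rep(NA_character_, length(aa)),
                     frame = rep(NA_integer_, length(aa)),
                     seg = rep(NA_integer_, length(aa)))
  aaSeq <- AAStringSet(gsub("\\*+$", "", as.character(aa)))
  .newProteinDb(c(sequences(db), aaSeq), rbind(entryMeta(db), cmeta))
}

#' Build the full concatenated search database
#'
#' Convenience wrapper: targets from six-frame translation, optional
#' contaminants, then reversed decoys of everything, concatenated in the
#' order targets, contaminants, decoys.
#'
#' @inheritParams buildTargetDb
#' @param contaminants Optional contaminant FASTA path or `AAStringSet`.
#' @return A [ProteinDb-class] with a 1:1 decoy:(target+contaminant)
#'   ratio.
#' @export
buildSearchDb <- function(x, minLen = 7L, annotatedOnly = FALSE,
                          contaminants = NULL) {
  db <- buildTargetDb(x, minLen = minLen, annotatedOnly = annotatedOnly)
  if (!is.null(contaminants)) db <- appendContaminants(db, contaminants)
  dec <- makeDecoys(db)
  out <- .newProteinDb(c(sequences(db), sequences(dec)),
                       rbind(entryMeta(db), entryMeta(dec)))
  message(sprintf("search database: %d target, %d contaminant, %d decoy",
                  sum(entryMeta(out)$category == "target"),
                  sum(entryMeta(out)$category == "contaminant"),
                  sum(entryMeta(out)$category == "decoy")))
  out
}

#' Write a search database as FASTA
#'
#' Writes entries in the canonical order targets, contaminants, decoys,
#' 60 columns wide; the output is byte-stable across runs on identical
#' input. Target-entry headers carry a `src=` token with the source
#' transcript id and the frame so [readSearchDb()] can reconstruct the
#' metadata.
#'
#' @param db A [ProteinDb-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeSearchDb <- function(db, file) {
  if (length(db) == 0L) {
    warning("writing an empty search database")
    writeLines(character(), file)
    return(invisible(file))
  }
  m <- entryMeta(db)
  o <- order(match(m$category, c("target", "contaminant", "decoy")))
  seqs <- sequences(db)[o]
  m <- m[o, , drop = FALSE]
  src <- ifelse(is.na(m$source_transcript), "",
                sprintf(" src=%s", m$source_transcript))
  names(seqs) <- paste0(m$entry_id, src)
  writeXStringSet(seqs, file, width = 60L)
  invisible(file)
}

#' Read a search database written by [writeSearchDb()]
#'
#' Reconstructs entry categories from the `REV_`/`CONT_` id prefixes and
#' target metadata from the `|frame=|seg=` id fields and the `src=`
#' header token.
#'
#' @param file FASTA path.
#' @return A [ProteinDb-class].
#' @export
readSearchDb <- function(file) {
  aa <- readAAStringSet(file)
  if (length(aa) == 0L)
    return(.newProteinDb(AAStringSet(), .emptyDbMeta()))
  hdr <- names(aa)
  src <- ifelse(grepl(" src=", hdr, fixed = TRUE),
                sub("^.* src=", "", hdr), NA_character_)
  id <- sub(" src=.*$", "", hdr)
  category <- ifelse(startsWith(id, "REV_"), "decoy",
                     ifelse(startsWith(sub("^REV_", "", id), "CONT_"),
                            "contaminant", "target"))
  category[startsWith(id, "REV_")] <- "decoy"
  base <- sub("^REV_", "", id)
  category[category != "decoy" & startsWith(base, "CONT_")] <- "contaminant"
  hasFrame <- grepl("\\|frame=[+-]?[0-9]\\|seg=[0-9]+$", id)
  frame <- rep(NA_integer_, length(id))
  seg <- rep(NA_integer_, length(id))
  frame[hasFrame] <- as.integer(sub("^.*\\|frame=([+-]?[0-9])\\|seg=.*$",
                                    "\\1", id[hasFrame]))
  seg[hasFrame] <- as.integer(sub("^.*\\|seg=([0-9]+)$", "\\1", id[hasFrame]))
  header <- sub("\\|frame=[+-]?[0-9]\\|seg=[0-9]+$", "", id)
  meta <- DataFrame(entry_id = id, header = header, category = category,
                    source_transcript = src, frame = frame, seg = seg)
  .newProteinDb(aa, meta)
}
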