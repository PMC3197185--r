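## Sequence primitives: reverse complement, frame translation and
## stop-delimited segment extraction for six-frame database construction.

.FRAMES <- c(1L, 2L, 3L, -1L, -2L, -3L)

## direct lookup against the standard code; codons containing N are not in
## the table and fall out as X. (Biostrings::translate rebuilds its fuzzy
## codon table on every call, which is prohibitive for six-frame scans.)
.CODE <- Biostrings::GENETIC_CODE

.translateNt <- function(s) {
  n <- nchar(s)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, 3L)
  aa <- .CODE[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## in-frame subsequence with the trailing partial codon dropped
.frameSub <- function(sequence, offset) {
  n <- nchar(sequence) - offset
  n <- n - n %% 3L
  if (n < 3L) "" else substr(sequence, offset + 1L, offset + n)
}

.checkNucleotide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single character string")
  bad <- regexpr("[^ACGTNacgtn]", sequence)
  if (bad > 0L)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  toupper(sequence)
}

#' Reverse complement of a nucleotide sequence
#'
#' Bases outside \{A, C, G, T, N\} are rejected with the position of the
#' first offending character; `N` complements to itself. Applying the
#' function twice returns the input.
#'
#' @param sequence Single nucleotide string (case-insensitive).
#' @return The reverse-complemented string, in upper case.
#' @examples
#' revComp("ATGC")  # "GCAT"
#' @export
revComp <- function(sequence) {
  sequence <- .checkNucleotide(sequence)
  if (!nzchar(sequence)) return("")
  as.character(reverseComplement(DNAStringSet(sequence))[[1L]])
}

#' Translate one reading frame
#'
#' Translates a nucleotide sequence in one of the six conceptual reading
#' frames using the standard genetic code. Frames `+1..+3` read the forward
#' strand starting at offsets 0..2; frames `-1..-3` read the reverse
#' complement likewise. A trailing partial codon is dropped, stop codons are
#' rendered `*`, and any codon containing `N` yields `X`.
#'
#' @param sequence Single nucleotide string over \{A,C,G,T,N\}.
#' @param frame Integer frame code in `c(1, 2, 3, -1, -2, -3)`.
#' @return Amino-acid string (possibly empty), stops as `*`.
#' @examples
#' translateFrame("ATGAAATAA", 1)   # "MK*"
#' translateFrame("ATGAAATAA", -1)  # "LFH"
#' @export
translateFrame <- function(sequence, frame) {
  sequence <- .checkNucleotide(sequence)
  if (length(frame) != 1L || !(frame %in% .FRAMES))
    stop("'frame' must be one of +1, +2, +3, -1, -2, -3")
  if (frame < 0L) sequence <- if (nzchar(sequence)) revComp(sequence) else ""
  .translateNt(.frameSub(sequence, abs(frame) - 1L))
}

#' Stop-delimited segments of all six frame translations
#'
#' Translates a transcript in all six frames, splits each translation at
#' stop codons and returns every stop-free segment of at least `minLen`
#' amino acids with its 1-based start position within the frame
#' translation. Segments in which more than `maxXFrac` of residues are `X`
#' (ambiguous codons) are dropped, as they cannot yield informative
#' peptides.
#'
#' @param sequence Single nucleotide string.
#' @param minLen Minimum segment length in amino acids (default 7, the
#'   shortest commonly searchable tryptic peptide).
#' @param maxXFrac Maximum tolerated fraction of `X` residues per segment
#'   (default 0.5).
#' @return `data.frame` with columns `frame` (integer code), `start_aa`
#'   (1-based position within the frame translation), `seg` (segment index
#'   within the frame, counted over retained segments) and `segment`
#'   (amino-acid string without `*`). Zero rows when nothing qualifies.
#' @examples
#' sixFrameSegments("ATGAAATAA", minLen = 2)
#' @export
sixFrameSegments <- function(sequence, minLen = 7L, maxXFrac = 0.5) {
  if (minLen < 1L) stop("'minLen' must be >= 1")
  sequence <- .checkNucleotide(sequence)
  rc <- if (nzchar(sequence)) revComp(sequence) else ""
  out <- vector("list", 6L)
  for (i in seq_along(.FRAMES)) {
    f <- .FRAMES[i]
    aa <- .translateNt(.frameSub(if (f > 0L) sequence else rc,
                                 abs(f) - 1L))
    if (!nzchar(aa)) next
    m <- gregexpr("[^*]+", aa)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    segs <- regmatches(aa, list(m))[[1L]]
    keep <- lens >= minLen
    if (any(keep)) {
      segs <- segs[keep]; starts <- starts[keep]
      nX <- nchar(segs) - nchar(gsub("X", "", segs, fixed = TRUE))
      keep2 <- nX / nchar(segs) <= maxXFrac
      if (any(keep2))
        out[[i]] <- data.frame(frame = f, start_aa = starts[keep2],
                               seg = seq_len(sum(keep2)),
                               segment = segs[keep2],
                               stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(frame = integer(), start_aa = integer(),
                      seg = integer(), segment = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
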