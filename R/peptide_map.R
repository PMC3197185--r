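## In-silico tryptic digestion and exact peptide-to-entry mapping.

#' In-silico tryptic digestion of one protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' enumerates all products with up to `missedMax` internal (missed)
#' cleavage sites and length within `[lenMin, lenMax]`. Duplicate peptide
#' sequences within one protein are reported once, with the smallest
#' missed-cleavage count.
#'
#' @param sequence Amino-acid string (no `*`).
#' @param missedMax Maximum missed cleavages (default 2).
#' @param lenMin,lenMax Peptide length bounds in amino acids (defaults 6
#'   and 50).
#' @return `data.frame` with columns `peptide`, `missed` and `start`
#'   (1-based position of the first reported occurrence).
#' @examples
#' digest("MKRGGK", missedMax = 0, lenMin = 1)$peptide  # MK, R, GGK
#' @export
digest <- function(sequence, missedMax = 2L, lenMin = 6L, lenMax = 50L) {
  if (missedMax < 0L) stop("'missedMax' must be >= 0")
  if (lenMin > lenMax) stop("'lenMin' must be <= 'lenMax'")
  n <- nchar(sequence)
  empty <- data.frame(peptide = character(), missed = integer(),
                      start = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  ## cleavage after position i: K/R at i, not followed by P
  cut <- which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
  bounds <- c(0L, cut, n)                      # base-peptide boundaries
  nb <- length(bounds) - 1L                    # number of base peptides
  res <- vector("list", missedMax + 1L)
  for (m in 0:min(missedMax, nb - 1L)) {
    i <- seq_len(nb - m)                       # first base peptide index
    from <- bounds[i] + 1L
    to <- bounds[i + m + 1L]
    len <- to - from + 1L
    keep <- len >= lenMin & len <= lenMax
    if (any(keep))
      res[[m + 1L]] <- data.frame(
        peptide = substring(sequence, from[keep], to[keep]),
        missed = m, start = from[keep], stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$missed, out$start), , drop = FALSE]
  out <- out[!duplicated(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an exact-match peptide-to-entry index over a database
#'
#' Digests every entry of a [ProteinDb-class] and records, for each
#' distinct peptide, the set of entries producing it as a tryptic product
#' under the given parameters. Leucine and isoleucine are distinct unless
#' `collapseIL = TRUE`, which maps both to `L` on indexing and lookup (for
#' inputs from engines that cannot distinguish them).
#'
#' @param db A [ProteinDb-class].
#' @inheritParams digest
#' @param collapseIL Treat I and L as equivalent (default `FALSE`).
#' @return A [PeptideIndex-class].
#' @export
buildPeptideIndex <- function(db, missedMax = 2L, lenMin = 6L,
                              lenMax = 50L, collapseIL = FALSE) {
  m <- entryMeta(db)
  seqs <- as.character(sequences(db))
  peps <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    p <- digest(seqs[[i]], missedMax, lenMin, lenMax)$peptide
    if (collapseIL) p <- unique(chartr("I", "L", p))
    peps[[i]] <- p
  }
  env <- list2env(split(rep(m$entry_id, lengths(peps)), unlist(peps)),
                  envir = new.env(parent = emptyenv(), hash = TRUE))
  new("PeptideIndex", env = env,
      params = list(missedMax = missedMax, lenMin = lenMin,
                    lenMax = lenMax, collapseIL = collapseIL))
}

#' Map observed peptides to database entries
#'
#' Exact-sequence lookup of observed peptides in a [PeptideIndex-class].
#' Peptides absent from the index are returned in `unmatched` rather than
#' dropped silently.
#'
#' @param observed Character vector of peptide sequences.
#' @param index A [PeptideIndex-class] built with the same digestion
#'   parameters as the search.
#' @return List with `matched` (named list: peptide -> character vector of
#'   entry ids, over the distinct matched peptides) and `unmatched`
#'   (character vector of distinct unmatched peptides).
#' @export
mapPeptides <- function(observed, index) {
  stopifnot(is(index, "PeptideIndex"))
  observed <- unique(observed)
  if (isTRUE(index@params$collapseIL)) observed <- unique(chartr("I", "L", observed))
  hits <- lapply(observed, get0, envir = index@env)
  found <- !vapply(hits, is.null, logical(1))
  list(matched = setNames(hits[found], observed[found]),
       unmatched = observed[!found])
}

#' Write the digested peptide table of a database
#'
#' TSV with one row per distinct peptide: sequence, number of parent
#' entries and the semicolon-joined parent entry ids.
#'
#' @param index A [PeptideIndex-class].
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
writePeptideTable <- function(index, file) {
  peps <- sort(ls(index@env))
  parents <- lapply(peps, get, envir = index@env)
  tab <- data.frame(peptide = peps,
                    n_parents = lengths(parents),
                    parent_ids = vapply(parents, function(p)
                      paste(sort(p), collapse = ";"), character(1)),
                    stringsAsFactors = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
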