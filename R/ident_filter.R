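## PSM table parsing, protein inference (grouping by indistinguishable
## peptide sets), threshold filtering and target-decoy FDR estimation.

.PSM_COLS <- c("spectrum_id", "peptide", "peptide_prob", "protein_prob",
               "sample", "condition", "replicate")

#' Read a peptide-spectrum-match table
#'
#' The canonical PSM exchange format is a TSV with a header row defining at
#' least the columns `spectrum_id`, `peptide`, `peptide_prob`,
#' `protein_prob`, `sample`, `condition` and `replicate`; extra columns are
#' carried through. Probabilities outside `[0, 1]` are rejected with their
#' line number.
#'
#' @param file Path to the TSV file.
#' @return `data.frame`, one row per PSM.
#' @export
readPsmTable <- function(file) {
  tab <- read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
  miss <- setdiff(.PSM_COLS, colnames(tab))
  if (length(miss))
    stop("PSM table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("peptide_prob", "protein_prob")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad))
      stop(sprintf("line %d: %s '%s' is not a probability in [0, 1]",
                   bad[1L] + 1L, col, tab[[col]][bad[1L]]))
    tab[[col]] <- v
  }
  tab$replicate <- as.integer(tab$replicate)
  tab
}

## group signature: the sorted observed-peptide set of an entry
.pepSignature <- function(peps) paste(sort(peps), collapse = "\r")

#' Infer protein groups from mapped PSMs
#'
#' Maps each PSM's peptide onto database entries via the peptide index and
#' merges entries whose observed peptide sets are identical (maximal
#' indistinguishable sets) into one protein group. A shared peptide counts
#' toward every group containing it. Spectral counts are tallied per
#' sample; the group probability is the maximum `protein_prob` over the
#' PSMs counted to it. PSMs whose peptide is absent from the index are set
#' aside (see `metadata(x)$unmatched_peptides`), never dropped silently.
#'
#' @param psms PSM `data.frame` from [readPsmTable()].
#' @param index A [PeptideIndex-class] over the concatenated search
#'   database.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `SpC` (groups x samples spectral counts), `rowData` columns
#'   `group_id`, `entry_ids` (semicolon-joined), `peptides`
#'   (semicolon-joined), `n_unique_peptides`, `protein_prob`, `category`,
#'   and `colData` columns `sample`, `condition`, `replicate`.
#' @export
inferProteins <- function(psms, index) {
  mp <- mapPeptides(psms$peptide, index)
  if (isTRUE(index@params$collapseIL))
    psms$peptide <- chartr("I", "L", psms$peptide)
  keep <- psms$peptide %in% names(mp$matched)
  psmsK <- psms[keep, , drop = FALSE]

  ## samples in deterministic order
  sampTab <- unique(psms[, c("sample", "condition", "replicate")])
  sampTab <- sampTab[order(sampTab$condition, sampTab$replicate,
                           sampTab$sample), , drop = FALSE]

  if (nrow(psmsK) == 0L) {
    se <- SummarizedExperiment(
      assays = list(SpC = matrix(0L, 0L, nrow(sampTab),
                                 dimnames = list(NULL, sampTab$sample))),
      rowData = DataFrame(group_id = character(), entry_ids = character(),
                          peptides = character(),
                          n_unique_peptides = integer(),
                          protein_prob = numeric(), category = character()),
      colData = DataFrame(sampTab, row.names = sampTab$sample))
    metadata(se)$unmatched_peptides <- mp$unmatched
    return(se)
  }

  ## entry -> observed peptide set
  entryPeps <- new.env(parent = emptyenv())
  for (p in names(mp$matched))
    for (e in mp$matched[[p]]) {
      cur <- get0(e, envir = entryPeps)
      assign(e, c(cur, p), envir = entryPeps)
    }
  entries <- sort(ls(entryPeps))
  sigs <- vapply(entries, function(e)
    .pepSignature(get(e, envir = entryPeps)), character(1))
  groups <- split(entries, sigs)
  ## deterministic group order: by smallest member entry id
  groups <- groups[order(vapply(groups, min, character(1)))]
  gid <- sprintf("G%05d", seq_along(groups))
  gPeps <- lapply(names(groups), function(s)
    strsplit(s, "\r", fixed = TRUE)[[1L]])

  ## peptide -> group indices
  pep2grp <- new.env(parent = emptyenv())
  for (g in seq_along(gPeps))
    for (p in gPeps[[g]]) {
      cur <- get0(p, envir = pep2grp)
      assign(p, c(cur, g), envir = pep2grp)
    }

  nG <- length(groups); nS <- nrow(sampTab)
  counts <- matrix(0L, nG, nS, dimnames = list(gid, sampTab$sample))
  prob <- numeric(nG)
  sIdx <- match(psmsK$sample, sampTab$sample)
  for (i in seq_len(nrow(psmsK))) {
    gs <- get(psmsK$peptide[i], envir = pep2grp)
    counts[gs, sIdx[i]] <- counts[gs, sIdx[i]] + 1L
    prob[gs] <- pmax(prob[gs], psmsK$protein_prob[i])
  }

  cat_of <- function(ids) {
    isRev <- startsWith(ids, "REV_")
    isCont <- startsWith(sub("^REV_", "", ids), "CONT_") & !isRev
    if (any(!isRev & !isCont)) "target"
    else if (any(isCont)) "contaminant"
    else "decoy"
  }
  rd <- DataFrame(
    group_id = gid,
    entry_ids = vapply(groups, function(e) paste(e, collapse = ";"),
                       character(1), USE.NAMES = FALSE),
    peptides = vapply(gPeps, function(p) paste(sort(p), collapse = ";"),
                      character(1)),
    n_unique_peptides = lengths(gPeps),
    protein_prob = prob,
    category = vapply(groups, cat_of, character(1), USE.NAMES = FALSE),
    row.names = gid)
  se <- SummarizedExperiment(assays = list(SpC = counts), rowData = rd,
                             colData = DataFrame(sampTab,
                                                 row.names = sampTab$sample))
  metadata(se)$unmatched_peptides <- mp$unmatched
  se
}

#' Filter identifications to acceptance thresholds
#'
#' Applies the two-stage acceptance rule: PSMs below the peptide-level
#' probability threshold are removed first, protein groups are re-inferred
#' from the surviving PSMs, and a group is then retained only if it has at
#' least `minPeptides` distinct peptides and a protein probability of at
#' least `minProteinProb`. Defaults are the two-peptide / 95% protein /
#' 50% peptide rule used to hold the identification FDR under 1%.
#'
#' @inheritParams inferProteins
#' @param minPeptides Minimum distinct peptides per protein group
#'   (default 2).
#' @param minProteinProb Minimum protein probability (default 0.95).
#' @param minPeptideProb Minimum peptide probability; lower-probability
#'   PSMs are discarded before grouping (default 0.50).
#' @return A filtered `SummarizedExperiment` as from [inferProteins()];
#'   `metadata()` records the thresholds.
#' @export
filterIdentifications <- function(psms, index, minPeptides = 2L,
                                  minProteinProb = 0.95,
                                  minPeptideProb = 0.50) {
  stopifnot(minPeptides >= 1L,
            minProteinProb >= 0, minProteinProb <= 1,
            minPeptideProb >= 0, minPeptideProb <= 1)
  psms <- psms[psms$peptide_prob >= minPeptideProb, , drop = FALSE]
  se <- inferProteins(psms, index)
  rd <- rowData(se)
  keep <- rd$n_unique_peptides >= minPeptides &
    rd$protein_prob >= minProteinProb
  se <- se[keep, ]
  metadata(se)$thresholds <- list(minPeptides = minPeptides,
                                  minProteinProb = minProteinProb,
                                  minPeptideProb = minPeptideProb)
  se
}

#' Target-decoy FDR of a filtered identification set
#'
#' Estimates the false discovery rate of a concatenated target-decoy
#' search from the group category labels. The default estimator is
#' decoys/targets; `method = "combined"` uses 2D/(T+D). Contaminant
#' groups are excluded from both counts. With no targets and no decoys
#' the FDR is 0; with decoys but no targets it is reported as 1 with a
#' warning.
#'
#' @param x A `SummarizedExperiment` from [inferProteins()] or
#'   [filterIdentifications()], or a character vector of category labels.
#' @param method `"ratio"` (D/T, default) or `"combined"` (2D/(T+D)).
#' @return FDR as a fraction in `[0, Inf)` (D/T can exceed 1 in
#'   degenerate inputs; 1.0 is reported when targets are absent).
#' @export
estimateFdr <- function(x, method = c("ratio", "combined")) {
  method <- match.arg(method)
  cats <- if (is.character(x)) x else rowData(x)$category
  nT <- sum(cats == "target")
  nD <- sum(cats == "decoy")
  if (nT == 0L) {
    if (nD == 0L) return(0)
    warning("no target groups but ", nD, " decoy group(s); FDR reported as 1")
    return(1)
  }
  if (method == "ratio") nD / nT else 2 * nD / (nT + nD)
}

#' Write a filtered identification table
#'
#' TSV with one row per group: id, member entries, peptide count, protein
#' probability, category and per-sample spectral counts.
#'
#' @param se `SummarizedExperiment` of identifications.
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
writeIdentificationTable <- function(se, file) {
  rd <- as.data.frame(rowData(se))
  counts <- assay(se, "SpC")
  colnames(counts) <- paste0("SpC.", colnames(counts))
  write.table(cbind(rd, counts), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
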