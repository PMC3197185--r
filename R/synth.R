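## Seeded synthetic-data generator: transcriptomes with embedded coding
## regions, mock best-hit annotation tables and replicate PSM tables whose
## spectra are multinomially sampled from ground-truth abundance x length
## (so NSAF, which divides by length, recovers molar abundance).

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

.randNt <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.AA20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")

.AA2CODON <- split(names(Biostrings::GENETIC_CODE),
                   unname(Biostrings::GENETIC_CODE))

.reverseTranslate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(.AA2CODON[aa], function(opts)
    opts[sample.int(length(opts), 1L)], character(1), USE.NAMES = FALSE),
    collapse = "")
}

#' Generate a synthetic transcriptome with known coding regions
#'
#' Each transcript embeds one stop-free coding region in a known reading
#' frame, flanked by in-frame stop codons and random untranslated ends, so
#' the ground-truth protein is recovered verbatim by
#' [sixFrameSegments()]. Half of the transcripts (in expectation) are
#' emitted in reverse orientation, exercising the negative frames.
#' Ground-truth relative molar abundances are drawn per condition;
#' planted fold changes are assigned to randomly chosen present proteins
#' such that each planted protein's deplete/replete NSAF ratio equals the
#' requested value exactly (the remaining proteins absorb a common
#' compensating factor).
#'
#' @param n Number of transcripts (>= 1).
#' @param proteinLenRange Coding-region length bounds in amino acids
#'   (default 100-300).
#' @param utrLenRange Flanking-sequence length bounds in nucleotides
#'   (default 30-300; with the defaults mean transcript length is close
#'   to the ~1 kb typical of de novo assemblies).
#' @param gc GC content of the non-coding flanks (default 0.5).
#' @param foldChanges Numeric vector of deplete/replete abundance ratios
#'   to plant, one protein each (default none).
#' @param nDepleteOnly Number of proteins absent under the replete
#'   condition but present under depletion (default 0).
#' @param presentFraction Fraction of proteins present in the samples at
#'   all; absent proteins get zero abundance in both conditions and serve
#'   as landing space for planted incorrect identifications
#'   (default 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return List with `transcripts` (named `DNAStringSet`) and `truth`
#'   (`data.frame`: `protein_id`, `transcript_id`, `cds_frame`,
#'   `length_aa`, `protein`, `present`, `planted`, `abund_replete`,
#'   `abund_deplete`, `planted_fold_change`).
#' @export
generateTranscriptome <- function(n, proteinLenRange = c(100L, 300L),
                                  utrLenRange = c(30L, 300L), gc = 0.5,
                                  foldChanges = numeric(),
                                  nDepleteOnly = 0L,
                                  presentFraction = 1, seed = 1L) {
  if (n < 1L) stop("'n' must be >= 1")
  if (proteinLenRange[1L] < 10L || proteinLenRange[1L] > proteinLenRange[2L])
    stop("infeasible protein length range")
  if (length(foldChanges) + nDepleteOnly > n * presentFraction)
    stop("more planted effects than present proteins")
  .withSeed(seed, {
    protLen <- sample(proteinLenRange[1L]:proteinLenRange[2L], n,
                      replace = TRUE)
    ## coding regions are redrawn until they yield at least one fully
    ## tryptic peptide of 6-50 aa, so simulated searches are feasible
    proteins <- vapply(protLen, function(L) {
      for (try in 1:50) {
        p <- paste(sample(.AA20, L, replace = TRUE), collapse = "")
        if (nrow(digest(p, 0L, 6L, 50L)) > 0L) return(p)
      }
      stop("could not draw a digestible protein of length ", L)
    }, character(1))
    seqs <- character(n); frames <- integer(n)
    for (i in seq_len(n)) {
      utr5 <- .randNt(sample(utrLenRange[1L]:utrLenRange[2L], 1L), gc)
      utr3 <- .randNt(sample(utrLenRange[1L]:utrLenRange[2L], 1L), gc)
      cds <- .reverseTranslate(proteins[i])
      tr <- paste0(utr5, "TAA", cds, "TAA", utr3)
      offset <- (nchar(utr5) + 3L) %% 3L      # 0-based CDS start offset
      f <- offset + 1L
      if (runif(1) < 0.5) {                   # reverse orientation
        tr <- revComp(tr)
        f <- -f
      }
      seqs[i] <- tr; frames[i] <- f
    }
    ids <- sprintf("Locus_%04d_Transcript_1", seq_len(n))
    present <- rep(FALSE, n)
    present[sample.int(n, round(n * presentFraction))] <- TRUE

    ## base weights; normalize replete over present, non-deplete-only
    w <- rexp(n) + 0.2
    w[!present] <- 0

    ## planted effects are assigned a common upper-quartile base
    ## abundance: spectral-count fold changes are only measurable above
    ## the reporting limit, and the generator is built for clean recovery
    fold <- rep(1, n)
    idxPresent <- which(present)
    k <- length(foldChanges) + nDepleteOnly
    special <- idxPresent[sample.int(length(idxPresent), k)]
    if (k > 0)
      w[special] <- stats::quantile(w[idxPresent], 0.75)
    idxFC <- head(special, length(foldChanges))
    idxDO <- tail(special, nDepleteOnly)
    fold[idxFC] <- foldChanges
    fold[idxDO] <- Inf
    wRep <- w; wRep[idxDO] <- 0
    wRep <- wRep / sum(wRep)
    wDep <- wRep
    wDep[idxFC] <- wRep[idxFC] * foldChanges
    wDep[idxDO] <- w[idxDO] / sum(w[present])   # modest deplete share
    specialIdx <- c(idxFC, idxDO)
    ordinary <- setdiff(idxPresent, specialIdx)
    cFac <- (1 - sum(wDep[specialIdx])) / sum(wRep[ordinary])
    if (cFac <= 0)
      stop("planted effects leave no abundance for background proteins")
    wDep[ordinary] <- wRep[ordinary] * cFac

    planted <- rep(FALSE, n)
    planted[special] <- TRUE
    truth <- data.frame(
      protein_id = sprintf("P%04d", seq_len(n)),
      transcript_id = ids, cds_frame = frames, length_aa = protLen,
      protein = proteins, present = present, planted = planted,
      abund_replete = wRep, abund_deplete = wDep,
      planted_fold_change = fold, stringsAsFactors = FALSE)
    list(transcripts = setNames(DNAStringSet(seqs), ids), truth = truth)
  })
}

.GENERIC_TITLES <- c("hypothetical protein", "predicted protein",
                     "conserved unknown protein", "ribosomal protein",
                     "heat shock protein", "photosystem II protein",
                     "chlorophyll a-b binding protein", "ferredoxin",
                     "ATP synthase subunit", "elongation factor")

#' Generate a mock best-hit annotation table
#'
#' Emulates tabular BLAST results against a reference nucleotide
#' database: a fraction `hitRate` of transcripts receive a qualifying
#' best hit (E-value below the 1e-3 rule, a `zeroEvalueRate` share of
#' them scored exactly 0.0); of the rest, half receive a non-qualifying
#' line and half no line at all. `duplicatePairs` pairs of annotated
#' transcripts are deliberately given identical subject headers to
#' exercise downstream deduplication.
#'
#' @param truth Ground-truth table from [generateTranscriptome()].
#' @param hitRate Fraction of transcripts with a qualifying hit
#'   (default 0.9).
#' @param zeroEvalueRate Fraction of qualifying hits scored E = 0
#'   (default 0.045).
#' @param duplicatePairs Number of planted duplicate-header pairs
#'   (default 1; skipped when fewer than 2 transcripts are annotated).
#' @param titles Optional named character vector (transcript id ->
#'   subject title) overriding the generic titles, e.g. to plant pathway
#'   enzyme names.
#' @param seed Integer seed.
#' @return Hit `data.frame` in the [readBlastTab()] layout.
#' @export
generateAnnotations <- function(truth, hitRate = 0.9,
                                zeroEvalueRate = 0.045,
                                duplicatePairs = 1L, titles = NULL,
                                seed = 1L) {
  stopifnot(hitRate >= 0, hitRate <= 1)
  .withSeed(seed, {
    n <- nrow(truth)
    hasHit <- runif(n) < hitRate
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      id <- truth$transcript_id[i]
      if (hasHit[i]) {
        ev <- if (runif(1) < zeroEvalueRate) 0
              else 10^(-runif(1, 3.2, 60))
        title <- if (!is.null(titles) && id %in% names(titles))
          titles[[id]] else
          paste(sample(.GENERIC_TITLES, 1L),
                sprintf("[synthetic taxon %d]", sample.int(40L, 1L)))
        rows[[i]] <- data.frame(
          query_id = id,
          subject_id = sprintf("ref|SYN%05d.1|", sample.int(99999L, 1L)),
          percent_identity = round(runif(1, 70, 100), 2),
          evalue = ev, bitscore = round(runif(1, 80, 1500), 1),
          subject_title = title, stringsAsFactors = FALSE)
      } else if (runif(1) < 0.5) {
        rows[[i]] <- data.frame(
          query_id = id,
          subject_id = sprintf("ref|SYN%05d.1|", sample.int(99999L, 1L)),
          percent_identity = round(runif(1, 40, 70), 2),
          evalue = 10^runif(1, -2.5, 0.7),
          bitscore = round(runif(1, 20, 60), 1),
          subject_title = paste(sample(.GENERIC_TITLES, 1L), "(weak)"),
          stringsAsFactors = FALSE)
      }
    }
    hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    ann <- which(truth$transcript_id %in%
                   hits$query_id[hits$evalue < 1e-3])
    if (duplicatePairs > 0L && length(ann) >= 2L) {
      for (k in seq_len(min(duplicatePairs, floor(length(ann) / 2)))) {
        pair <- truth$transcript_id[ann[c(2L * k - 1L, 2L * k)]]
        src <- which(hits$query_id == pair[1L] & hits$evalue < 1e-3)[1L]
        dst <- which(hits$query_id == pair[2L] & hits$evalue < 1e-3)[1L]
        hits$subject_id[dst] <- hits$subject_id[src]
        hits$subject_title[dst] <- hits$subject_title[src]
      }
    }
    rownames(hits) <- NULL
    attr(hits, "seed") <- seed
    hits
  })
}

#' Write hits as tabular BLAST output (outfmt 6 + title)
#'
#' Serializes a hit table in the 13-column layout read by
#' [readBlastTab()], filling the alignment bookkeeping columns with
#' placeholder coordinates. The generating seed, when recorded on the
#' table, is written as a leading comment.
#'
#' @param hits Hit `data.frame` ([readBlastTab()] layout).
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
writeBlastTab <- function(hits, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(attr(hits, "seed")))
    writeLines(sprintf("# TransProteo synthetic annotation; seed=%d",
                       attr(hits, "seed")), con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    writeLines(paste(h$query_id, h$subject_id, h$percent_identity,
                     100L, 0L, 0L, 1L, 100L, 1L, 100L,
                     format(h$evalue, scientific = TRUE, digits = 3),
                     h$bitscore, h$subject_title, sep = "\t"), con)
  }
  invisible(file)
}

#' Sample spectral counts from ground-truth abundances
#'
#' Per sample, `depth` spectra are allocated to the present proteins by
#' multinomial sampling with weights abundance x length (longer proteins
#' yield more peptides, so observed counts scale with both; NSAF divides
#' the length back out).
#'
#' @param truth Ground-truth table from [generateTranscriptome()].
#' @param depth Spectra per sample (default 5000).
#' @param replicates Replicates per condition (default 3).
#' @param conditions Condition labels (default `c("replete",
#'   "deplete")`, matching the `abund_*` columns).
#' @param seed Integer seed.
#' @return List with `counts` (proteins x samples integer matrix, rows
#'   named by `protein_id`) and `samples` (`data.frame`: `sample`,
#'   `condition`, `replicate`).
#' @export
simulateCounts <- function(truth, depth = 5000L, replicates = 3L,
                           conditions = c("replete", "deplete"),
                           seed = 1L) {
  if (depth < 1L) stop("'depth' must be >= 1")
  .withSeed(seed, {
    samples <- expand.grid(replicate = seq_len(replicates),
                           condition = conditions,
                           stringsAsFactors = FALSE)[, 2:1]
    samples$sample <- paste0(samples$condition, "_", samples$replicate)
    counts <- matrix(0L, nrow(truth), nrow(samples),
                     dimnames = list(truth$protein_id, samples$sample))
    for (s in seq_len(nrow(samples))) {
      ab <- truth[[paste0("abund_", samples$condition[s])]]
      wt <- ab * truth$length_aa
      if (sum(wt) <= 0) stop("no protein has positive abundance")
      counts[, s] <- rmultinom(1L, depth, wt)[, 1L]
    }
    list(counts = counts, samples = samples)
  })
}

#' Simulate replicate PSM tables from a search database
#'
#' Emulates the output of a concatenated target-decoy search. Correct
#' spectra are allocated to present proteins by [simulateCounts()]'s
#' abundance-x-length multinomial and assigned uniformly to the tryptic
#' peptides of the protein's database entry, with high peptide and
#' protein probabilities. Incorrect spectra are planted at known rates:
#' a `decoyHitRate` fraction lands uniformly on decoy entries and a
#' `falseTargetRate` fraction uniformly on target entries of absent
#' proteins (the two landing spaces are size-matched 1:1, so the
#' decoy-based FDR estimator is calibrated against the planted truth);
#' both receive low-mean probabilities.
#'
#' @param db The concatenated [ProteinDb-class] built from the synthetic
#'   transcriptome.
#' @param truth Ground-truth table from [generateTranscriptome()].
#' @param depth Spectra per sample (default 5000).
#' @param replicates Replicates per condition (default 3).
#' @param conditions Condition labels (default replete/deplete).
#' @param decoyHitRate Fraction of spectra planted on decoy entries
#'   (default 0).
#' @param falseTargetRate Fraction planted on absent-protein target
#'   entries (default `decoyHitRate`; requires absent proteins in
#'   `truth` when positive).
#' @param missedMax,lenMin,lenMax Digestion parameters used to draw
#'   peptides (defaults 2, 6, 50).
#' @param seed Integer seed.
#' @return PSM `data.frame` in the [readPsmTable()] layout, plus a
#'   `truth_class` column (`correct`, `decoy`, `false_target`).
#' @export
simulatePsms <- function(db, truth, depth = 5000L, replicates = 3L,
                         conditions = c("replete", "deplete"),
                         decoyHitRate = 0, falseTargetRate = decoyHitRate,
                         missedMax = 2L, lenMin = 6L, lenMax = 50L,
                         seed = 1L) {
  stopifnot(decoyHitRate >= 0, decoyHitRate < 1,
            falseTargetRate >= 0, decoyHitRate + falseTargetRate < 1)
  m <- entryMeta(db)
  seqs <- as.character(sequences(db))
  tgt <- which(m$category == "target")
  truthEntry <- tgt[match(truth$protein, seqs[tgt])]
  if (anyNA(truthEntry))
    stop("ground-truth protein not found in database: ",
         truth$protein_id[which(is.na(truthEntry))[1L]])

  pepsOf <- new.env(parent = emptyenv())
  getPeps <- function(entryIdx) {
    key <- as.character(entryIdx)
    p <- get0(key, envir = pepsOf)
    if (is.null(p)) {
      p <- digest(seqs[entryIdx], missedMax, lenMin, lenMax)$peptide
      assign(key, p, envir = pepsOf)
    }
    p
  }
  presentIdx <- which(truth$present &
                        (truth$abund_replete > 0 | truth$abund_deplete > 0))
  for (i in presentIdx)
    if (length(getPeps(truthEntry[i])) == 0L)
      stop("present protein has no tryptic peptide within length bounds: ",
           truth$protein_id[i])

  absentIdx <- which(!truth$present)
  falseSpace <- truthEntry[absentIdx]                 # absent CDS entries
  decoySpace <- if (length(absentIdx))                # size-matched decoys
    match(paste0("REV_", m$entry_id[falseSpace]), m$entry_id)
  else which(m$category == "decoy")
  decoySpace <- decoySpace[!is.na(decoySpace)]
  if (falseTargetRate > 0 && !length(falseSpace))
    stop("falseTargetRate > 0 requires absent proteins in the ground truth")
  if (decoyHitRate > 0 && !length(decoySpace))
    stop("decoyHitRate > 0 requires decoy entries in the database")

  .withSeed(seed, {
    samples <- expand.grid(replicate = seq_len(replicates),
                           condition = conditions,
                           stringsAsFactors = FALSE)[, 2:1]
    samples$sample <- paste0(samples$condition, "_", samples$replicate)
    out <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      nClass <- rmultinom(1L, depth,
                          c(1 - decoyHitRate - falseTargetRate,
                            decoyHitRate, falseTargetRate))[, 1L]
      recs <- list()
      ## correct spectra: abundance x length multinomial over proteins
      ab <- truth[[paste0("abund_", samples$condition[s])]]
      wt <- ab * truth$length_aa
      spc <- rmultinom(1L, nClass[1L], wt)[, 1L]
      hot <- which(spc > 0L)
      if (length(hot)) {
        pep <- unlist(lapply(hot, function(i) {
          pp <- getPeps(truthEntry[i])
          pp[sample.int(length(pp), spc[i], replace = TRUE)]
        }))
        recs[[1L]] <- data.frame(
          peptide = pep,
          peptide_prob = pmin(rbeta(length(pep), 30, 1.5), 1),
          protein_prob = runif(length(pep), 0.95, 1),
          truth_class = "correct", stringsAsFactors = FALSE)
      }
      ## planted incorrect spectra
      plant <- function(space, nSpec, label) {
        if (nSpec == 0L) return(NULL)
        ent <- space[sample.int(length(space), nSpec, replace = TRUE)]
        pep <- vapply(ent, function(e) {
          pp <- getPeps(e)
          if (!length(pp)) return(NA_character_)
          pp[sample.int(length(pp), 1L)]
        }, character(1))
        ok <- !is.na(pep)
        if (!any(ok)) return(NULL)
        data.frame(peptide = pep[ok],
                   peptide_prob = rbeta(sum(ok), 1.2, 4),
                   protein_prob = runif(sum(ok), 0, 1),
                   truth_class = label, stringsAsFactors = FALSE)
      }
      recs[[2L]] <- plant(decoySpace, nClass[2L], "decoy")
      recs[[3L]] <- plant(falseSpace, nClass[3L], "false_target")
      tab <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
      tab$spectrum_id <- sprintf("%s_S%06d", samples$sample[s],
                                 seq_len(nrow(tab)))
      tab$sample <- samples$sample[s]
      tab$condition <- samples$condition[s]
      tab$replicate <- samples$replicate[s]
      out[[s]] <- tab
    }
    res <- do.call(rbind, out)
    res <- res[, c("spectrum_id", "peptide", "peptide_prob",
                   "protein_prob", "sample", "condition", "replicate",
                   "truth_class")]
    rownames(res) <- NULL
    attr(res, "seed") <- seed
    res
  })
}

#' Write a PSM table as TSV
#'
#' Serializes PSMs in the layout read by [readPsmTable()]; a recorded
#' generating seed is written as a leading comment.
#'
#' @param psms PSM `data.frame`.
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
writePsmTable <- function(psms, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(attr(psms, "seed")))
    writeLines(sprintf("# TransProteo synthetic PSMs; seed=%d",
                       attr(psms, "seed")), con)
  suppressWarnings(
    write.table(psms, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(file)
}
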