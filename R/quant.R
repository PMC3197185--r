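## NSAF spectral-count quantification, normalization, fold changes and
## one-way ANOVA on replicate NSAF values.

#' Attach protein-group lengths from the search database
#'
#' The length used in NSAF is the length of the longest member entry of a
#' group (members of an indistinguishable group share their observed
#' peptides, so one representative length must stand for the group).
#'
#' @param se `SummarizedExperiment` of identifications.
#' @param db The [ProteinDb-class] the identifications were searched
#'   against.
#' @return `se` with a `rowData` column `L` (amino acids).
#' @export
addProteinLengths <- function(se, db) {
  w <- setNames(width(sequences(db)), entryMeta(db)$entry_id)
  rd <- rowData(se)
  rowData(se)$L <- vapply(strsplit(rd$entry_ids, ";", fixed = TRUE),
    function(ids) {
      miss <- setdiff(ids, names(w))
      if (length(miss))
        stop("group member missing from database: ", miss[1L])
      max(w[ids])
    }, numeric(1))
  se
}

#' Scale spectral counts to a reference condition's totals
#'
#' Multiplies each sample's counts by (mean total spectral count over the
#' reference-condition samples) / (that sample's total), so all samples
#' are put on the reference condition's scale while the reference mean is
#' preserved.
#'
#' @param se `SummarizedExperiment` with assay `SpC`.
#' @param referenceCondition Condition whose mean total defines the scale.
#' @return `se` with an added assay `SpC_norm`.
#' @export
normalizeCounts <- function(se, referenceCondition) {
  cond <- colData(se)$condition
  if (!referenceCondition %in% cond)
    stop("reference condition '", referenceCondition,
         "' not present among samples")
  totals <- colSums(assay(se, "SpC"))
  if (any(totals == 0))
    stop("sample with zero total spectral count: ",
         names(totals)[totals == 0][1L])
  ref <- mean(totals[cond == referenceCondition])
  assay(se, "SpC_norm") <- sweep(assay(se, "SpC"), 2, ref / totals, "*")
  se
}

#' Normalized spectral abundance factors for one sample
#'
#' NSAF_k = (SpC_k / L_k) / sum_i (SpC_i / L_i): each protein's spectral
#' count is divided by its length (SAF) and scaled so the factors sum to 1
#' within the sample.
#'
#' @param spc Non-negative spectral counts (at least one positive).
#' @param len Protein lengths in amino acids (all positive).
#' @return Numeric vector of NSAF values summing to 1.
#' @examples
#' nsaf(c(4, 6), c(100, 300))  # 2/3, 1/3
#' @export
nsaf <- function(spc, len) {
  if (length(spc) != length(len)) stop("'spc' and 'len' lengths differ")
  if (any(len <= 0)) stop("protein lengths must be positive")
  if (any(spc < 0)) stop("spectral counts must be non-negative")
  saf <- spc / len
  tot <- sum(saf)
  if (tot == 0) stop("all spectral counts are zero; NSAF undefined")
  saf / tot
}

#' Compute per-sample NSAF values over an identification set
#'
#' Applies [nsaf()] column-wise, using the group lengths from
#' [addProteinLengths()]. Contaminant and decoy groups are excluded from
#' the quantified set (and from the NSAF denominator) by default, per the
#' purpose of the contaminant database.
#'
#' @param se `SummarizedExperiment` with assay `SpC` and `rowData$L`.
#' @param assayName Which count assay to use (default `"SpC"`; use
#'   `"SpC_norm"` after [normalizeCounts()]).
#' @param targetsOnly Drop decoy and contaminant groups before computing
#'   (default `TRUE`).
#' @return The (possibly subset) `se` with an added assay `NSAF`.
#' @export
computeNsaf <- function(se, assayName = "SpC", targetsOnly = TRUE) {
  if (is.null(rowData(se)$L))
    stop("rowData(se)$L missing; call addProteinLengths() first")
  if (targetsOnly) se <- se[rowData(se)$category == "target", ]
  counts <- assay(se, assayName)
  res <- vapply(seq_len(ncol(counts)),
                function(j) nsaf(counts[, j], rowData(se)$L),
                numeric(nrow(counts)))
  assay(se, "NSAF") <- matrix(res, nrow = nrow(counts),
                              dimnames = dimnames(counts))
  se
}

#' Fold change with zero-abundance sentinels
#'
#' The ratio of the mean deplete-condition NSAF to the mean
#' replete-condition NSAF. When one side is zero the ratio is undefined;
#' instead of an infinity, a sentinel is returned together with a
#' one-sided bound obtained by substituting a pseudo-count NSAF
#' (`pseudoNsaf`, the NSAF a protein would have at `pseudoSpC` spectra)
#' for the zero side — mirroring reporting such as "greater than 100-fold
#' increase" for proteins undetected in one condition.
#'
#' @param nsafDeplete Mean NSAF under the deplete condition.
#' @param nsafReplete Mean NSAF under the replete condition.
#' @param pseudoNsaf NSAF value substituted for a zero side when forming
#'   the bound.
#' @return List with `type` (`"ratio"`, `"deplete_only"`,
#'   `"replete_only"` or `"absent"`) and `fc` (the ratio, the one-sided
#'   bound, or `NA` for `absent`).
#' @export
foldChange <- function(nsafDeplete, nsafReplete, pseudoNsaf = NA_real_) {
  stopifnot(nsafDeplete >= 0, nsafReplete >= 0)
  if (nsafDeplete > 0 && nsafReplete > 0)
    list(type = "ratio", fc = nsafDeplete / nsafReplete)
  else if (nsafDeplete > 0)
    list(type = "deplete_only", fc = nsafDeplete / pseudoNsaf)
  else if (nsafReplete > 0)
    list(type = "replete_only", fc = pseudoNsaf / nsafReplete)
  else list(type = "absent", fc = NA_real_)
}

#' Classical one-way ANOVA
#'
#' F statistic and p-value of the one-way fixed-effects analysis of
#' variance with (k-1, N-k) degrees of freedom, via
#' [stats::oneway.test()] with pooled variance. Degenerate layouts are
#' resolved explicitly: zero between-group variance gives F = 0, p = 1;
#' zero within-group variance with distinct group means gives F = Inf,
#' p = 0.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/vector of group labels, same length; at least 2
#'   groups with at least 2 observations each.
#' @return List with elements `F` and `p`.
#' @export
anovaOneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("at least two groups are required")
  if (any(table(groups) < 2L))
    stop("every group needs at least two replicates")
  means <- tapply(values, groups, mean)
  ssb <- sum(tapply(values, groups, length) * (means - mean(values))^2)
  ssw <- sum((values - means[groups])^2)
  if (ssb <= .Machine$double.eps * sum(values^2 + 1))
    return(list(F = 0, p = 1))
  if (ssw == 0)
    return(list(F = Inf, p = 0))
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value))
}

#' Differential abundance table between two conditions
#'
#' For every quantified protein group: mean NSAF per condition, the
#' deplete/replete fold change (or a zero-side sentinel with its
#' pseudo-count bound), a one-way ANOVA p-value computed on
#' `ln(NSAF + epsilon)` across replicates, and a significance flag at
#' `p <= alpha`. Rows are ordered with sentinel fold changes first, then
#' by descending fold change. A group is additionally flagged `abundant`
#' when its summed raw spectral count exceeds `abundantSpC` (the
#' detection limit being a single spectral count).
#'
#' @param se `SummarizedExperiment` with assays `SpC` and `NSAF` (from
#'   [computeNsaf()]).
#' @param conditionDeplete,conditionReplete Condition labels (defaults
#'   `"deplete"`, `"replete"`).
#' @param alpha Significance level; the boundary is inclusive
#'   (default 0.05).
#' @param pseudoSpC Pseudo spectral count used for sentinel bounds
#'   (default 0.5 spectra).
#' @param epsilon Offset inside the log transform (default 1e-9).
#' @param logTransform Compute the ANOVA on `ln(NSAF + epsilon)`
#'   (default `TRUE`); `FALSE` uses raw NSAF.
#' @param padjMethod Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; default `"none"`, matching a per-protein
#'   p <= alpha rule (set `"BH"` for Benjamini-Hochberg).
#' @param abundantSpC Summed-count threshold for the `abundant` flag
#'   (default 10 spectra).
#' @return `data.frame` with columns `group_id`, `nsaf_mean_replete`,
#'   `nsaf_mean_deplete`, `fc_type`, `fold_change`, `F`, `p_value`,
#'   `significant`, `abundant`, `total_SpC`.
#' @export
differentialTable <- function(se, conditionDeplete = "deplete",
                              conditionReplete = "replete", alpha = 0.05,
                              pseudoSpC = 0.5, epsilon = 1e-9,
                              logTransform = TRUE, padjMethod = "none",
                              abundantSpC = 10) {
  cond <- colData(se)$condition
  if (!all(c(conditionDeplete, conditionReplete) %in% cond))
    stop("both conditions must be present among samples")
  two <- cond %in% c(conditionDeplete, conditionReplete)
  se <- se[, two]
  cond <- colData(se)$condition
  nsafM <- assay(se, "NSAF")
  spc <- assay(se, "SpC")
  L <- rowData(se)$L
  dep <- cond == conditionDeplete
  rep_ <- cond == conditionReplete
  mDep <- rowMeans(nsafM[, dep, drop = FALSE])
  mRep <- rowMeans(nsafM[, rep_, drop = FALSE])

  ## per-sample SAF denominators, for pseudo-count NSAF bounds
  safSum <- colSums(spc / L)
  pseudoDep <- rowMeans(outer(pseudoSpC / L, safSum[dep], "/"))
  pseudoRep <- rowMeans(outer(pseudoSpC / L, safSum[rep_], "/"))

  n <- nrow(se)
  fcType <- character(n); fc <- numeric(n)
  pv <- numeric(n); Fv <- numeric(n)
  y <- if (logTransform) log(nsafM + epsilon) else nsafM
  for (i in seq_len(n)) {
    r <- foldChange(mDep[i], mRep[i],
                    pseudoNsaf = if (mRep[i] == 0) pseudoRep[i]
                                 else pseudoDep[i])
    fcType[i] <- r$type; fc[i] <- r$fc
    a <- anovaOneway(y[i, ], cond)
    pv[i] <- a$p; Fv[i] <- a$F
  }
  pv <- stats::p.adjust(pv, method = padjMethod)
  out <- data.frame(
    group_id = rowData(se)$group_id,
    nsaf_mean_replete = mRep, nsaf_mean_deplete = mDep,
    fc_type = fcType, fold_change = fc, F = Fv, p_value = pv,
    significant = pv <= alpha,
    total_SpC = rowSums(spc),
    stringsAsFactors = FALSE)
  out$abundant <- out$total_SpC > abundantSpC
  sentinel <- out$fc_type %in% c("deplete_only", "replete_only")
  out <- out[order(-sentinel, -out$fold_change, out$group_id,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
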