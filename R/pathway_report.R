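## Mapping quantified protein groups onto the fatty-acid / TAG pathway
## roster and rendering the abundance report.

#' Load a pathway enzyme definition
#'
#' Reads a YAML pathway configuration: a list of enzymes, each with
#' `abbrev`, `full_name`, `pathway` (`fatty_acid`, `TAG` or
#' `regulatory`), `keywords` (matched case-insensitively against
#' annotation headers) and optional `ec_numbers`. The packaged default
#' (`system.file("extdata", "fa_tag_pathway.yaml", package =
#' "TransProteo")`) encodes the fatty-acid and triacylglycerol
#' biosynthesis roster (ACCase through DGAT plus the AMPK regulator).
#'
#' @param path YAML file; default the packaged roster.
#' @return `data.frame` with one row per enzyme and a list column
#'   `keywords`.
#' @export
loadPathwayConfig <- function(path = system.file("extdata",
                                                 "fa_tag_pathway.yaml",
                                                 package = "TransProteo")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$enzymes) || !length(cfg$enzymes))
    stop("pathway config defines no enzymes")
  abbrev <- vapply(cfg$enzymes, function(e) as.character(e$abbrev %||% ""),
                   character(1))
  if (any(!nzchar(abbrev))) stop("every enzyme needs an 'abbrev'")
  if (anyDuplicated(abbrev))
    stop("duplicate enzyme abbreviation: ", abbrev[duplicated(abbrev)][1L])
  kw <- lapply(cfg$enzymes, function(e) as.character(unlist(e$keywords)))
  ec <- lapply(cfg$enzymes, function(e) as.character(unlist(e$ec_numbers)))
  hasAny <- lengths(kw) > 0L | lengths(ec) > 0L
  if (any(!hasAny))
    stop("enzyme without keywords or EC numbers: ", abbrev[!hasAny][1L])
  out <- data.frame(
    abbrev = abbrev,
    full_name = vapply(cfg$enzymes, function(e)
      as.character(e$full_name %||% NA_character_), character(1)),
    pathway = vapply(cfg$enzymes, function(e)
      as.character(e$pathway %||% NA_character_), character(1)),
    stringsAsFactors = FALSE)
  bad <- !out$pathway %in% c("fatty_acid", "TAG", "regulatory")
  if (any(bad))
    stop("unknown pathway label for ", out$abbrev[bad][1L])
  out$keywords <- kw
  out$ec_numbers <- ec
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign protein groups to pathway enzymes by header keywords
#'
#' Case-insensitive substring matching of enzyme keywords against the
#' annotation-derived header of each group. A group is assigned to at most
#' one enzyme: when several keywords match, the longest matching keyword
#' wins, so a group is never counted in two pathway rows. Enzymes with no
#' matching group are reported with empty sets.
#'
#' @param headers Character vector of group headers, named by group id.
#' @param enzymes Enzyme table from [loadPathwayConfig()].
#' @return Named list, one element per enzyme abbreviation, each a
#'   character vector of group ids (possibly empty).
#' @export
matchEnzymes <- function(headers, enzymes) {
  if (is.null(names(headers)))
    stop("'headers' must be named by group id")
  res <- setNames(vector("list", nrow(enzymes)), enzymes$abbrev)
  for (i in seq_along(res)) res[[i]] <- character()
  hLow <- tolower(headers)
  for (g in seq_along(headers)) {
    bestEnz <- NA_integer_; bestLen <- -1L
    for (i in seq_len(nrow(enzymes))) {
      for (k in enzymes$keywords[[i]]) {
        if (nchar(k) > bestLen && grepl(tolower(k), hLow[g], fixed = TRUE)) {
          bestEnz <- i; bestLen <- nchar(k)
        }
      }
    }
    if (!is.na(bestEnz))
      res[[bestEnz]] <- c(res[[bestEnz]], names(headers)[g])
  }
  res
}

#' Pathway abundance report
#'
#' One row per enzyme of the pathway definition: mean NSAF per condition
#' scaled by 1e5 (the conventional display scale for NSAF in pathway
#' figures), the fold change or its sentinel bound, the ANOVA p-value and
#' significance flag. Enzymes with no matched protein group are marked
#' `not identified`. When several groups match one enzyme, the group with
#' the highest total spectral count represents it (`n_groups` reports the
#' multiplicity).
#'
#' @param diff Differential table from [differentialTable()].
#' @param enzymeMap Named list from [matchEnzymes()].
#' @param enzymes Enzyme table from [loadPathwayConfig()].
#' @return `data.frame` with columns `abbrev`, `full_name`, `pathway`,
#'   `status`, `group_id`, `n_groups`, `nsaf_replete_1e5`,
#'   `nsaf_deplete_1e5`, `fc_display`, `fold_change`, `fc_type`,
#'   `p_value`, `significant`.
#' @export
pathwayTable <- function(diff, enzymeMap, enzymes) {
  rows <- lapply(seq_len(nrow(enzymes)), function(i) {
    ab <- enzymes$abbrev[i]
    gids <- intersect(enzymeMap[[ab]], diff$group_id)
    base <- data.frame(abbrev = ab, full_name = enzymes$full_name[i],
                       pathway = enzymes$pathway[i],
                       stringsAsFactors = FALSE)
    if (!length(gids))
      return(cbind(base, data.frame(
        status = "not identified", group_id = NA_character_,
        n_groups = 0L, nsaf_replete_1e5 = NA_real_,
        nsaf_deplete_1e5 = NA_real_, fc_display = NA_character_,
        fold_change = NA_real_, fc_type = NA_character_,
        p_value = NA_real_, significant = NA,
        stringsAsFactors = FALSE)))
    d <- diff[diff$group_id %in% gids, , drop = FALSE]
    d <- d[order(-d$total_SpC, d$group_id), , drop = FALSE][1L, ]
    disp <- if (d$fc_type == "ratio") sprintf("%.1f", d$fold_change)
            else if (d$fc_type == "absent") "absent"
            else sprintf(">%.1f%s", d$fold_change,
                         if (d$fc_type == "replete_only") " (down)" else "")
    cbind(base, data.frame(
      status = "identified", group_id = d$group_id,
      n_groups = length(gids),
      nsaf_replete_1e5 = d$nsaf_mean_replete * 1e5,
      nsaf_deplete_1e5 = d$nsaf_mean_deplete * 1e5,
      fc_display = disp, fold_change = d$fold_change,
      fc_type = d$fc_type, p_value = d$p_value,
      significant = d$significant, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a pathway report as plain text
#'
#' @param tab Table from [pathwayTable()].
#' @return Character vector of lines (invisibly printed with `cat()` when
#'   interactive use is intended).
#' @export
formatPathwayReport <- function(tab) {
  lines <- c(sprintf("%-8s %-11s %-14s %10s %10s %10s %8s",
                     "enzyme", "pathway", "status", "NSAFx1e5.R",
                     "NSAFx1e5.D", "fold", "p"))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    lines <- c(lines, sprintf(
      "%-8s %-11s %-14s %10s %10s %10s %8s", r$abbrev, r$pathway,
      r$status,
      ifelse(is.na(r$nsaf_replete_1e5), "-",
             sprintf("%.2f", r$nsaf_replete_1e5)),
      ifelse(is.na(r$nsaf_deplete_1e5), "-",
             sprintf("%.2f", r$nsaf_deplete_1e5)),
      ifelse(is.na(r$fc_display), "-", r$fc_display),
      ifelse(is.na(r$p_value), "-", sprintf("%.3g", r$p_value))))
  }
  lines
}
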