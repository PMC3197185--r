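# Independent brute-force oracles. These deliberately share no code with
# the package: plain-R codon table, character-by-character logic.

.ORACLE_CODE <- local({
  codes <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  codes
})

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  paste(rev(unname(comp[chars])), collapse = "")
}

oracleTranslate <- function(s, frame) {
  s <- toupper(s)
  if (frame < 0) s <- oracleRevComp(s)
  off <- abs(frame) - 1L
  aa <- character()
  i <- off + 1L
  while (i + 2L <= nchar(s)) {
    codon <- substr(s, i, i + 2L)
    aa <- c(aa, if (grepl("N", codon)) "X"
            else unname(.ORACLE_CODE[codon]))
    i <- i + 3L
  }
  paste(aa, collapse = "")
}

oracleSixFrame <- function(s, minLen, maxXFrac = 0.5) {
  rows <- list()
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- oracleTranslate(s, f)
    if (!nzchar(aa)) next
    chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
    start <- NA_integer_; segN <- 0L
    flush <- function(start, end) {
      seg <- substr(aa, start, end)
      nX <- sum(strsplit(seg, "", fixed = TRUE)[[1L]] == "X")
      if (nchar(seg) >= minLen && nX / nchar(seg) <= maxXFrac) {
        segN <<- segN + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          frame = f, start_aa = start, seg = segN, segment = seg,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_along(chars)) {
      if (chars[i] == "*") {
        if (!is.na(start)) flush(start, i - 1L)
        start <- NA_integer_
      } else if (is.na(start)) start <- i
    }
    if (!is.na(start)) flush(start, length(chars))
  }
  if (!length(rows))
    return(data.frame(frame = integer(), start_aa = integer(),
                      seg = integer(), segment = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# textbook one-way fixed-effects ANOVA, computed from the sums of squares
oracleAnova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    v <- values[groups == lev]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fst, p = pf(Fst, k - 1, N - k, lower.tail = FALSE))
}

randomDna <- function(len, withN = FALSE) {
  alpha <- if (withN) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, len, replace = TRUE,
               prob = if (withN) c(rep(0.23, 4), 0.08) else NULL),
        collapse = "")
}

randomProtein <- function(len) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa20, len, replace = TRUE), collapse = "")
}

# minimal hand-built protein database for unit tests
makeTestDb <- function(seqs, categories = rep("target", length(seqs)),
                       headers = names(seqs)) {
  meta <- S4Vectors::DataFrame(
    entry_id = names(seqs), header = headers, category = categories,
    source_transcript = ifelse(categories == "target", "tx1", NA),
    frame = ifelse(categories == "target", 1L, NA_integer_),
    seg = ifelse(categories == "target", 1L, NA_integer_))
  aa <- Biostrings::AAStringSet(unname(seqs))
  names(aa) <- names(seqs)
  methods::new("ProteinDb", aa = aa, meta = meta)
}

# minimal PSM table in the canonical column layout
makePsms <- function(peptides, sample = "replete_1",
                     condition = "replete", replicate = 1L,
                     peptide_prob = 0.99, protein_prob = 0.99) {
  n <- length(peptides)
  data.frame(
    spectrum_id = sprintf("%s_S%04d", sample, seq_len(n)),
    peptide = peptides,
    peptide_prob = rep_len(peptide_prob, n),
    protein_prob = rep_len(protein_prob, n),
    sample = rep_len(sample, n), condition = rep_len(condition, n),
    replicate = rep_len(replicate, n), stringsAsFactors = FALSE)
}
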