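---
title: "Methods: transcriptome-derived search databases and NSAF quantification"
author: "TransProteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-derived search databases and NSAF quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TransProteo)
library(SummarizedExperiment)
```

# The problem and the model

For organisms without a sequenced genome, MS/MS spectra are usually
searched against the proteins of sequenced relatives. Peptides that are
not conserved across that evolutionary distance simply cannot be matched,
so whole pathways appear "absent" even when their enzymes are abundant.
The alternative implemented here treats the organism's own de novo
assembled transcriptome as the proteome search model: every assembled
transcript is conceptually translated in all six reading frames, the
resulting stop-free segments become the target search space, and the
experimental spectra are matched against that space instead. Because
assembled transcripts carry no reliable reading-frame or strand
information, six-frame translation is the model's deliberate
over-approximation: the correct coding segment is guaranteed to be in the
database, at the cost of roughly five junk segments per real one. The
cost is controlled downstream by the probability filters and the
target-decoy FDR estimate, not upstream by ORF prediction — this package
intentionally has no start-codon or codon-usage model.

The pipeline is: annotation transfer → six-frame database with reversed
decoys and contaminants → peptide-to-protein mapping → protein grouping
and threshold filtering with FDR estimation → NSAF quantification and
differential statistics → pathway report.

# Annotation transfer

Tabular BLAST results (the canonical 12-column layout, optional 13th
title column) are reduced to one best hit per transcript: minimum
E-value strictly below `1e-3`, ties broken by higher bitscore and then
lexicographically by subject id so the choice is order-independent.
Qualifying transcripts take `subject_id + " " + subject_title` as their
header; the rest keep their assembly id. Whether annotation-less
transcripts belong in the search database at all is genuinely ambiguous
in practice; we retain them by default (the conservative superset — a
spectrum can only match what is present) and expose `annotatedOnly =
TRUE` for the restrictive reading.

Duplicate headers arise whenever several transcripts share a best hit
(isoforms, paralogs, fragmented assemblies). They are made unique by
ascending numbering in input order: the first occurrence is kept
verbatim, later ones get `_2`, `_3`, … — keeping the first header stable
means the numbering never renames a transcript retroactively.

The annotation summary reports the annotation rate over all transcripts
and the zero-E-value share over annotated transcripts, each rounded to
one decimal. On the published counts this recomputes 315/7,067 = 4.5%,
one tenth of a point above the 4.4% in the original report — the
discrepancy is documented rather than silently matched, since the
original rounding basis is unknown.

# The search database

Each stop-free six-frame segment of at least `minLen = 7` amino acids
becomes a target entry `"<header>|frame=<f>|seg=<n>"`. Seven residues is
the shortest tryptic peptide that is commonly considered searchable;
the limit is configurable because search engines differ. Codons
containing `N` translate to `X`, and segments that are more than half
`X` are dropped — they cannot produce informative peptides but would
inflate the decoy space. Stop codons always split (no read-through),
which is standard six-frame database practice.

Decoys are whole-sequence reversals — matching the "forward and
reverse" concatenated-database design — with ids prefixed `REV_`;
shuffled decoys are out of scope. Reversal preserves amino-acid
composition and length exactly, which is what makes the decoy space a
fair model of random matching. Contaminant proteins (cRAP-style) are
appended with `CONT_` ids *before* decoy generation, so contaminants are
decoyed like ordinary entries and the FDR estimator treats them
uniformly; contaminant-matching groups are nevertheless excluded from
the FDR counts and from biological result tables, since their purpose is
only to absorb spectra that would otherwise be misassigned. Entry order
(input order, frames +1..+3 then −1..−3, then position; targets,
contaminants, decoys in the file) is deterministic so the database is
reproducible byte for byte.

Frame translation is a direct lookup against the standard genetic code
table shipped with Biostrings (`GENETIC_CODE`); the generic
`Biostrings::translate()` rebuilds its fuzzy-codon table on every call,
which is prohibitive when scanning thousands of transcripts six times
each, and its initiator-codon convention (TTG/CTG → M at position 1)
is wrong for internal six-frame segments.

# Peptide mapping and identification filtering

The in-silico digest cleaves C-terminally to K or R except before P,
with up to `missedMax = 2` missed cleavages and products of 6–50 amino
acids — typical engine settings, used here as conventions since mapping
only has to be consistent between index and search. Peptides map by
exact sequence; I and L are distinct by default because engine-resolved
sequences are assumed, with an optional `collapseIL` for inputs where
the engine cannot tell them apart. Unmatched peptides are reported,
never dropped silently.

Protein inference merges entries with identical observed peptide sets
into one group (the maximal-indistinguishable-set convention); shared
peptides count toward every group containing them. The acceptance rule
is applied in two stages in a fixed order: PSMs below the 50%
peptide-probability threshold are removed first, groups are re-formed,
and only then are the two-peptide and 95% protein-probability
requirements enforced — so a protein whose second peptide was
low-confidence is correctly rejected. "Two peptides" means two distinct
peptide sequences, the standard reading of the rule. Protein
probabilities are taken from the input columns, not recomputed: Bayesian
protein-probability modelling is a non-goal, and the synthetic generator
emits calibrated probabilities instead.

FDR is estimated as decoys/targets over filtered groups (the
concatenated-search estimator; `method = "combined"` gives 2D/(T+D)),
with contaminant groups excluded from both counts. A group is a decoy
only if *all* its members are decoys.

# Quantification

A protein group's length is its longest member's — group members are
indistinguishable on the observed peptides, and the longest member is
the conservative denominator for SpC/L. Spectral counts can first be
scaled so every sample matches the mean total of a reference condition
(the nitrogen-deplete samples by convention here); the reference's mean
total is preserved exactly. We read "normalization to the reference
condition's total spectral counts" as mean-of-replicates rather than a
pooled total; the two differ only by a common factor that NSAF divides
out anyway.

NSAF is SAF = SpC/L rescaled to sum to one per sample. Consequently it
is invariant under uniform per-sample count scaling, which the tests
assert, and the per-sample sum is checked to 1e-9.

Fold changes are ratios of mean NSAF, deplete over replete. When one
condition has zero counts the ratio is undefined; instead of infinities
the table carries a sentinel (`deplete_only` / `replete_only`) plus a
one-sided bound obtained by substituting a 0.5-spectrum pseudo-count
into the zero side — the same shape of statement as "greater than
100-fold increase" for a protein undetected under replete conditions.
0.5 is half the limit of detection of one spectral count, the usual
continuity-correction choice.

Significance comes from classical one-way ANOVA across replicates on
`ln(NSAF + 1e-9)` (raw-scale available via `logTransform = FALSE`); the
offset is far below any observable NSAF yet keeps zeros finite.
Degenerate layouts are resolved explicitly: no between-group variance
gives F = 0, p = 1; zero within-group variance with distinct means gives
F = ∞, p = 0. The boundary is inclusive (`p <= alpha` is significant,
with alpha = 0.05), and no multiple-testing correction is applied by
default, matching the per-protein reporting convention; Benjamini–
Hochberg is available via `padjMethod = "BH"`. Groups with more than 10
summed spectra carry an `abundant` flag, the limit of detection being a
single spectral count.

Rows are ordered sentinels first, then by descending fold change — the
table is a "what went up under depletion" view; use `fc_type` and the
p-value columns for other orderings.

# Pathway report

The packaged YAML roster covers the fatty-acid synthesis cycle, the
glycerol-path TAG assembly enzymes and the AMPK regulator, with
full names and EC numbers. Matching is case-insensitive keyword
containment against the annotation-derived group headers, and a group is
assigned to at most one enzyme — the longest matching keyword wins — so
no group is counted in two pathway rows. When several groups match one
enzyme the highest-total-count group represents it and the multiplicity
is reported. NSAF values are displayed ×10^5, the conventional scale for
pathway-figure annotation; report values are exactly the quant-module
NSAF times 1e5. The keyword matcher is a reconstruction of what is in
practice a manual, annotation-driven assignment; it claims consistency,
not identity, with any particular published mapping.

# The synthetic-data generator

The generator exists so that every stage can be validated against a
known ground truth without any external download.

* **Transcripts.** Each transcript is random UTR + in-frame stop + coding
  region + stop + UTR, with the coding region reverse-translated from a
  random protein of 100–300 amino acids through random synonymous codons,
  and the whole construct reverse-complemented with probability 1/2. The
  flanking stops guarantee the ground-truth protein is recovered verbatim
  by six-frame segmentation; coding regions are redrawn until they yield
  at least one fully tryptic peptide of 6–50 aa so simulated searches are
  always feasible. With 30–300 nt UTRs the mean transcript length is
  near 1 kb, typical of de novo assemblies.
* **Abundances.** Base weights are exponential with a small floor,
  normalized per condition. Planted fold changes are constructed so the
  planted protein's deplete/replete NSAF ratio equals the requested value
  *exactly*, with background proteins absorbing a common compensating
  factor; planted proteins are assigned a common upper-quartile base
  abundance, since spectral-count fold changes are only reliably
  measurable above the reporting limit and the generator is explicitly
  designed to make parameter recovery a clean test surface.
* **Spectra.** Per sample, spectra are multinomially allocated with
  weights abundance × length — longer proteins yield more peptides — so
  NSAF, which divides the length back out, estimates molar abundance.
  Each protein's spectra are assigned uniformly to its tryptic peptides.
  Correct PSMs get high peptide probabilities (Beta(30, 1.5)) and protein
  probabilities above 0.95; planted incorrect PSMs get low-mean
  probabilities (Beta(1.2, 4)) and uniform protein probabilities.
* **Planted errors.** Incorrect spectra land uniformly on decoy entries
  (`decoyHitRate`) and on coding-region entries of proteins absent from
  the samples (`falseTargetRate`). The two landing spaces are
  deliberately size-matched — the decoys of exactly those absent
  entries — so the decoy count is an unbiased estimate of the planted
  false-target count and the FDR estimator can be checked for
  calibration rather than merely for direction.
* **Seeding.** All randomness flows from one explicit seed; generated
  tables record it in a header comment, and identical seeds reproduce
  byte-identical files.

What the simulation does *not* emulate: spectrum-level physics (m/z,
retention time, dynamic exclusion), shared peptides between homologous
real proteins, probability miscalibration of real engines, and
compositional biases of real transcriptomes. Passing the synthetic
tests therefore demonstrates the correctness of the pipeline's
arithmetic and estimators under the stated sampling model, not search
engine performance on real spectra.

# Numerical choices and problem sizes

The test suite checks six-frame segmentation against a brute-force
re-implementation on hundreds of random sequences (exact equality),
ANOVA against the textbook F formula to 1e-10, NSAF conservation to
1e-9, and threshold monotonicity of the filter. FDR calibration pools
20 simulated searches over an 80-transcript database with half the
proteome absent and compares the decoy-based estimate with the planted
false-target rate inside the binomial 95% interval. Parameter recovery
plants ratios 2, 5 and 10 among 200 proteins at 5,000 spectra per
sample and 3 replicates per condition and requires the NSAF estimate
within ±25% in at least 90% of 50 seeded runs; end-to-end ranking runs
the full pipeline on 50-transcript assemblies across 20 seeds. These
sizes were chosen as the smallest at which the statistical assertions
have adequate power.

# Known limitations

* Protein inference is exact-match and sequence-level only;
  modifications, semi-tryptic products and mass tolerances live in the
  upstream engine, not here.
* The decoy estimator is the simple D/T ratio; at very small filtered
  set sizes its granularity (one decoy among tens of targets) makes
  single-run FDR values coarse, which is why calibration is assessed
  pooled across simulations.
* Keyword-based enzyme assignment inherits every ambiguity of the
  annotation headers; a curated mapping should override it for serious
  pathway claims (supply your own YAML).
* With only 2–3 replicates per condition the ANOVA p-values carry little
  power and the per-protein `p <= 0.05` rule makes no multiplicity
  adjustment; treat the significance flags as a screen, not an error
  rate guarantee.
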