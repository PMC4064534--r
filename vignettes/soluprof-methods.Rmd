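---
title: "Methods: categorical profiling of soluble cell-free expression"
author: "soluprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorical profiling of soluble cell-free expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soluprof)
```

## The categorical model

Cell-free synthesis in a bacterial extract, run under one uniform set of
conditions, assigns every target sequence to exactly one of three
categories: soluble product above a yield threshold (**A**), expressed
full-length but insoluble (**C**), and non-expressed (**N**).  The model
rests on two assumptions: that uniform reaction conditions make the outcome
a function of the sequence (plus noise), and that the three categories are
mutually exclusive and exhaustive.  `assignCategory()` encodes the scoring
rules:

* A ⇔ expressed ∧ full-length ∧ soluble yield > threshold,
* C ⇔ expressed ∧ full-length ∧ soluble yield ≤ threshold,
* N ⇔ not expressed ∨ truncated (product below the expected molecular
  size, which cannot attain proper structure or function).

The yield threshold defaults to 0.1 mg per ml of extract — below this level
a product band is not reliably distinguishable from the endogenous extract
proteins on a stained gel.  **Boundary rule**: a yield exactly equal to the
threshold is scored C; the A definition is "more than" the threshold.
Mixed soluble/insoluble expression is represented solely through the
reported soluble yield against the threshold; no separate "both fractions"
state exists, which keeps the categories a partition.  Replicate
experiments with conflicting outcomes are reconciled upstream; the
container accepts one outcome per id.

Sequences are restricted to the 20 standard residues.  Ambiguity codes
(B, Z, X), selenocysteine, stops and gaps are rejected rather than mapped,
because every downstream feature scale (hydropathy, mass, pKa, propensity)
is undefined for them; `readExpressionDataset(dropInvalid = TRUE)` instead
skips such records with a warning.

## Feature battery

### Physicochemical features

Computed exactly from the sequence: length; average molecular weight (sum
of average residue masses + 18.0153 Da); amino-acid composition; net charge
at pH 7 from the Henderson–Hasselbalch sum over ionizable groups (termini
plus C, D, E, H, K, R, Y); pI as the unique zero of that strictly
decreasing titration curve, found by bisection on (0, 14) to
|charge| < 1e-4 (cap 200 iterations — unreachable for a monotone curve);
and GRAVY, the mean Kyte–Doolittle hydropathy.  The pKa set defaults to the
EMBOSS values (N-terminus 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5,
K 10.8, R 12.5, Y 10.1); `physchemConfig()` accepts any other set (e.g.
Bjellqvist) since published pI values differ by pKa convention.  The
hydrophobicity scale is likewise swappable; Kyte–Doolittle is the
documented default.  Charged-residue features count K+R and D+E (histidine
is excluded from the pH-7 counts but participates in the titration);
correlation uses the per-length *densities* so that sequence length does
not confound.

### Motif and PTM-site features

A from-scratch PROSITE-syntax engine supports literals, `x`, `[..]`,
`{..}`, `(n)`, `(n,m)`, `<`, `>` and `-` separators.  Matching reports one
match per matching start position (overlaps allowed); at a start where
variable repeats allow several widths, repeats are resolved lazily —
earlier elements take their minimal count first — which is exactly the
backtracking order of a lazy regular expression, the property the test
suite exploits with an independent regex-translation oracle.  Coordinates
are 1-based inclusive.  Variable patterns are compiled to an ordered set of
fixed-width expansions (capped at 4096) so scanning is vectorized.

The bundled catalogue (`inst/extdata/motif_catalogue.tsv`, editable,
`name<TAB>pattern<TAB>kind`) carries the classical consensus patterns for
N-glycosylation, glycosaminoglycan attachment, PKA/PKC/CK2/tyrosine-kinase
phosphosites, N-myristoylation, amidation, Asx hydroxylation and a
C-terminal CAAX prenylation box; the tyrosine-sulfation entry is a
simplified acidic-context consensus and is labelled synthetic in the file.
The skip-flag convention some scanners apply to high-probability patterns
is deliberately not emulated: all matches are reported.  Each pattern
yields a presence flag (yes/no feature) and, for `count`-kind patterns, a
discrete site count.

### Structural features

* **PEST regions**: maximal stretches ≥ 12 residues between positively
  charged flanks (K/R/H, or the sequence ends) containing ≥ 1 P, ≥ 1 of
  D/E and ≥ 1 of S/T, scored
  `0.55 × mole%(D,E,P,S,T) − 0.5 × rescaled hydropathy`, with mean
  Kyte–Doolittle hydropathy mapped from [−4.5, 4.5] onto 0–90.  Scores
  above +5 are conventionally interesting; the threshold is a parameter,
  the feature reported is the region count and maximal score.
* **Coiled coils**: the sliding-window heptad method — for every 28-residue
  window (four heptads) and each of the 7 registers, the geometric mean of
  position-specific propensities; a residue's score is the maximum over
  covering windows and registers, segments are runs ≥ 1.3.  The propensity
  table is bundled as an editable text file; it is the package's own
  calibrated set in the spirit of the classical method (hydrophobics
  enriched at a/d, charged residues at e/g, proline strongly penalized),
  and the probability conversion of the original tools is omitted so the
  feature stays a deterministic, auditable score.
* **Baseline transmembrane / disorder**: a 19-residue hydropathy window at
  cutoff 1.6 (merged overlapping windows, counted), and a 21-residue
  running mean of a TOP-IDP-style disorder propensity scale thresholded at
  0.05 (fraction of positions above).  These are transparent baselines and
  carry a `baseline_` prefix in every output so they are never mistaken
  for the output of trained predictors (which, along with solvent
  accessibility, secondary structure, signal peptides, disulfide bonds and
  site-specific ubiquitination/SUMOylation/palmitoylation predictors, enter
  only through the `loadExternalFeatures()` adapter TSV).

## Correlation and significance

Features are analyzed by declared kind:

* **yes/no** — per category *k*, the 2×2 table (present/absent ×
  in-*k*/not-in-*k*) is tested with Fisher's exact test; the direction is
  the sign of (odds ratio − 1).  The two-sided p sums hypergeometric
  probabilities of all tables with the observed margins whose probability
  does not exceed the observed one (minimum-likelihood rule, relative tie
  tolerance 1e-7, log-space factorials).  A constant feature is ND.
* **discrete / continuous** — the feature is binned: one bin per observed
  value with left-to-right merging of adjacent sparse values until each
  bin holds ≥ `minBin` records (default 20; a trailing sparse bin merges
  backwards), or quantile bins (default 10; tied quantiles collapse so
  ties stay in one bin).  Quantile rather than equal-width binning
  stabilizes per-bin percentages under skewed feature distributions.  For
  each category the per-bin percentage is paired with the bin
  representative — the (count-weighted) value for discrete bins, the
  within-bin mean for continuous ones, a choice documented because
  correlating against bin indices instead would weight the range
  differently.  Pearson's *r* over the *n* bins is referred to
  *t* = *r*·√((n−2)/(1−r²)) with n−2 df; the one-tailed p takes its
  direction from the observed sign.  Fewer than 3 bins ⇒ ND.

Smoothing (`smoothProfile()`, centered moving average with edge-shrinking
window) is presentation-only by default: correlation uses the unsmoothed
profile unless `smoothWindow > 1` is requested.  A moving average was
chosen over a spline because it is order-independent and parameter-light.

The **sign call** per feature × category is: `+`/`−` for a significant
positive/negative full-range correlation; `±` when the full range is not
significant but the lower-half and upper-half bins (sharing the middle bin
when the count is odd; each half needs ≥ 3 bins) are individually
significant with opposite signs — an operational definition of a
non-monotone (U/V-shaped) association; `ND` otherwise.  `±` and `ND` have
no universally agreed definition in this kind of summary table; the
half-split rule was chosen because it is reproducible and testable, without
claiming fidelity to any particular published table.  α defaults to 0.05
per feature (no multiple-testing correction, matching the per-feature
convention of the analysis); Benjamini–Hochberg adjusted p-values are
reported alongside for the reader.

## The synthetic generator

`generateSyntheticDataset()` emulates an expression screen of a few
thousand sequences: lengths uniform on 50–300 residues, residues i.i.d.
from an average vertebrate composition, optional motif instances planted at
uniform positions in a configurable fraction of sequences (C-terminal for
end-anchored patterns).  Categories are drawn from a multinomial logit
whose baseline log-odds reproduce the configured base rates and whose
per-category shifts are β·z(feature) with the feature z-standardized over
the batch — a logit rather than threshold model because it yields smooth
monotone percentage curves, the structure the profile analysis assumes.
Outcomes are then back-filled consistently (A: yield threshold + an
exponential excess with mean 5× threshold; C: uniform below threshold; N:
non-expressed, with 30% of N records instead expressed-but-truncated) so
the categorical-assessment code path is exercised end to end rather than
bypassed.  One RNG stream per `generate` call, seeded from the config,
makes datasets bit-for-bit reproducible.

Base rates default to A = 0.257 — the benchmark soluble-expression success
rate for human proteins in *E. coli* extracts — with the remainder split
C = 0.343 / N = 0.400, reflecting that undetectable outcomes are typically
the largest class in such screens; the split is configurable and nothing
downstream depends on it.

What the generator does **not** emulate: domain architecture, homology
structure, composition–length coupling, batch effects, or measurement
noise in the yield itself.  Passing recovery tests on these data therefore
shows that the statistical machinery detects monotone sequence–category
associations at realistic scale; it does not validate any biological claim
about real expression screens.

## Numerical choices and problem sizes

* Fisher tie tolerance 1e-7 (relative), matching the common convention;
  log-space `lchoose` keeps totals up to 1e6 exact to ~1e-14.
* pI bisection tolerance 1e-4 on charge ⇒ agreement with a 0.001-pH grid
  scan to < 0.01 pH units (verified exhaustively in the tests).
* Degenerate inputs: constant features ⇒ ND with a warning; zero-variance
  category percentages ⇒ ND; profiles with < 3 bins ⇒ ND; sequences
  shorter than a window ⇒ all-zero profile (coiled coil) or no segments
  (TM).
* Validation problem sizes, chosen to give stable estimates at interactive
  runtimes: the Fisher sweep covers all 46,375 tables with total ≤ 30;
  null calibration uses 500 replicates of n = 2000; planted-sign recovery
  uses 20 seeds at n = 3000 with β = 1; the motif oracle runs 1000 random
  300-residue sequences against the full catalogue.

## Known limitations

* The baseline TM/disorder features are deliberately simple and should not
  be compared numerically against trained predictors; use the adapter for
  real predictor output.
* The coiled-coil propensity table is a calibrated stand-in, not the
  constant set of any published tool; segment calls at the default
  threshold 1.3 are conservative.
* The pattern catalogue is a small consensus set; pattern-based PTM-site
  prediction has high false-positive rates by construction, which the
  categorical analysis tolerates (it compares categories, not site truth).
* Per-feature α = 0.05 without correction reproduces the analysis
  convention but inflates family-wise error over a large feature battery;
  consult the reported BH column when screening many features.
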