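---
title: "Methods: iTRAQ 4-plex quantitation, CiR-C aggregation and sigma-tier significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iTRAQ 4-plex quantitation, CiR-C aggregation and sigma-tier significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqr)
```

## The measurement model

An iTRAQ 4-plex experiment tags the tryptic peptides of four drug-exposure
conditions with isobaric labels. Each fragmented peptide yields four reporter
ions at nominal m/z 114.1112, 115.1083, 116.1116 and 117.1150 Da, whose
intensities are proportional to the peptide amount contributed by each
condition. The package models one reporter measurement as

    I_c = base * fold(condition(c)) * exp(eps),   eps ~ N(0, noise_sd_log)

where `base` is the peptide's overall abundance/ionization scale,
`fold(cond)` is the protein's true expression ratio of that condition to the
reference (vehicle) condition, and the multiplicative log-normal term
collects labelling, fragmentation and detector noise. Ratios against the
reference channel cancel `base`, which is why all downstream inference works
on ratios, never on absolute intensities.

Two instrument-level corrections precede ratio formation:

* **Window extraction.** Reporter intensities are summed over all peaks
  within a mass tolerance (default 0.05 Da) of each nominal mass. Summation
  (rather than apex picking) was chosen because it is additive in the peak
  list and robust to peak splitting by the centroiding step; the tolerance
  must stay below half the inter-channel spacing (~0.5 Da) or the windows
  would overlap, and the extractor refuses such configurations.
* **Isotope-impurity correction.** Each tag's signal leaks partially into
  neighbouring channels (−2/−1/+1/+2 Da satellites). With `M[i, j]` the
  fraction of tag j observed in channel i, the true signals solve
  `M x = observed`. `M` is built from per-lot impurity percentages; the
  shipped file `inst/extdata/itraq4_correction_factors.tsv` carries
  representative placeholder values and is meant to be replaced by the
  vendor certificate of the actual reagent lot. Negative solutions (noise
  around small signals) are clipped to zero and counted for QC. Synthetic
  data is generated without impurity mixing, so the pipeline applies the
  correction only when a matrix is supplied.

## CiR-C: filtering, frequency index, medians

The filtering cascade removes, in order: (a) records whose identification
score is not strictly above 30 (a Mascot-style score, −10·log10 of the
random-match probability, so 30 corresponds to p ≈ 0.05); (b) records with
any null ratio — a 0.0 or uncalculable ratio caused by a missing/zero
reporter channel; (c) records annotated `Fragment` or `REVERSED` (decoy
database entries). The strictness of the score inequality matters at the
boundary and is tested explicitly.

Retained records are catalogued by (peptide sequence, accession). Keying on
the pair rather than the sequence alone keeps shared peptides from merging
distinct proteins, at the price of conservative protein inference — a
deliberate choice, as is collapsing modified forms to the bare sequence.
The **frequency index** of a pair is the number of distinct replicate
experiments in which it survived filtering; duplicates within an experiment
add ratio observations but not index. The quantified set is restricted to
pairs at (at least) a required index — the default demands presence in all
replicates, which is what makes the downstream medians cross-replicate
reproducible quantities rather than single-run estimates.

Protein ratios are medians of peptide ratios: the **overall** median pools
all (experiment, peptide) observations of an accession and condition; the
**series-specific** median is taken within one experiment. Pooling (rather
than a median of per-series medians) uses every observation with its natural
weight and is the reading adopted here; with balanced designs the two agree
closely. Even observation counts take the mean of the two central values.
The median tolerates gross corruption of up to half minus one of a protein's
peptide ratios, which is the practical defence against residual
mis-assignments.

## The Gaussian null and sigma tiers

Most proteins are unaffected by treatment, so the central mode of the ratio
frequency distribution estimates the null. The distribution is binned
(default width 0.05, chosen to resolve a null of SD ≈ 0.1 into ~12
informative bins at calibration sample sizes of a few hundred; exposed as a
parameter) and `A exp(−(r − m)² / 2 s²)` is fitted by Levenberg–Marquardt
nonlinear least squares, initialized from histogram moments. The fit object
is a standard S3 model with `print`, `summary`, `coef`, `predict`,
`residuals`, `simulate` and `plot` methods; `R² = 1 − SS_res/SS_tot` on bin
counts summarizes fit quality, and fits on fewer than three nonzero bins are
refused rather than attempted.

Classification uses the six boundaries `m ± k·s`, k ∈ 1..3. With the
calibrated null (m = 1.02, s = 0.10) they are 0.72, 0.82, 0.92, 1.12, 1.22,
1.32. The interval conventions are half-open and mirror-symmetric:

| tier | interval |
|------|----------|
| +3σ | r ≥ m+3s |
| +2σ | m+2s ≤ r < m+3s |
| +σ  | m+s ≤ r < m+2s |
| none | m−s ≤ r < m+s |
| −σ  | m−2s < r < m−s |
| −2σ | m−3s < r ≤ m−2s |
| −3σ | r ≤ m−3s |

so every positive ratio maps to exactly one tier and the assignment is
monotone in r. The source convention mixes ≤ and < at the down-side
boundaries; the scheme above preserves those stated inequalities and
resolves the remaining ambiguity by symmetry (the published classification
paragraph, not the mislabelled threshold list, is treated as authoritative).

**Fitted vs calibrated thresholds.** `run_pipeline()` classifies against the
null fitted to the current run's ratio distribution by default, and accepts
fixed `null_mean`/`null_sd` instead. The fixed path mirrors how such
thresholds are used in practice: the null is calibrated once on a reference
ratio set and the resulting boundaries are applied as constants thereafter.
Re-fitting per run adds calibration uncertainty of order `s/√n` to every
boundary; with a few hundred proteins that is ±0.005–0.015 on the ratio
scale, enough to flip proteins lying within that distance of a boundary.
Exact tier recovery on noise-free data is therefore only a meaningful
expectation under calibrated thresholds, and that is how the package's
end-to-end exactness checks are run; the fitted path is validated separately
by parameter-recovery and sign-recovery checks, which are insensitive to
boundary-width calibration error.

## Over-representation of protein classes

For a class with `n_class` of `n_ref` reference proteins and an input list
of `n_in` proteins, the expected count is `n_in · n_class / n_ref`, the fold
enrichment is observed/expected, and the direction is over (+) when observed
exceeds expected. Significance uses the one-sided exact binomial tail
(`P(X ≥ obs)` over, `P(X ≤ obs)` under, `X ~ Binomial(n_in, n_class/n_ref)`),
the historical default of protein-class over-representation tools; Fisher's
exact test is available as an option. Bonferroni correction multiplies by
`m` — defaulting to the number of classes actually observed in the input,
since classes with no observed members are not tested — and retention is
strict (`p_corrected < alpha`). Because the multiplier convention of any
given external tool release is not recoverable from a printed table, the
package treats expected counts and fold enrichments (fully determined by the
printed integers) as reproducible quantities and p-values as
convention-dependent.

## Clustering

The protein × condition matrix of overall median ratios (complete rows
only) is clustered agglomeratively on Euclidean distances. Average linkage
is the default — the common default of heat-map tools — with complete and
single linkage available; no row/column standardization is applied by
default since ratios are already on a common dimensionless scale. Rows-only
clustering is the default, column clustering optional. The merge sequence
and heights are validated against an exhaustive nearest-pair simulation in
the tests, and the ordered matrix and a newick rendering of the dendrogram
are the exported artefacts.

## The synthetic-data generator

The generator emulates the study design end to end: 5 independent replicate
experiments; 4 conditions rotated over the 4 channels with a different
tag/condition association per experiment; several peptides per protein
(truncated geometric, minimum 1, mean ≈ 2.9); base intensities log-uniform
over 10³–10⁶ (a realistic reporter dynamic range); per-channel log-normal
noise (default SD 0.05 on the log scale, a typical reporter CV); missing
channels, decoy annotations and sub-threshold scores at configurable rates
(defaults 5%, 5%, 10%); identification scores from a gamma distribution
shifted so that the sub-threshold probability is exact by construction.

Ground truth assigns one true fold per protein, applied to every
non-reference condition (a single per-protein tier label is only coherent
with a shared fold; per-condition effects would need per-condition labels).
Unregulated proteins draw their fold from the Gaussian null N(1.02, 0.10) —
untruncated, so the simulated ratio distribution converges to the null the
significance module assumes — and the tier label is obtained by classifying
the true fold under the generating thresholds, so a null protein that lands
beyond ±σ by chance is labelled truthfully rather than "none". Regulated
proteins sit at tier-band midpoints (`m + sign·(k + 0.5)·s`), evenly cycled
over k ∈ {1, 2, 3} and both signs.

The tag rotation uses cyclic shifts for experiments 1–4; a pure cyclic shift
over four conditions repeats at the fifth experiment, so experiments 5–8
apply the same shifts to the reversed condition order, giving eight
pairwise-distinct channel/condition bijections before recycling. The actual
associations used in any historical experiment being unknowable from a
methods description, the rotation is a convention and is recorded in each
PSM table's metadata.

All randomness flows from one integer seed; per-experiment sub-seeds are
derived arithmetically, so individual experiments are reproducible in
isolation and whole studies are byte-identical under a fixed seed.

**What the generator does not emulate:** chromatographic elution and
fractionation, isotope envelopes beyond the four reporter channels,
peptide-level interference/co-isolation (ratio compression), shared peptides
between proteins, and intensity-dependent noise. Passing tests on synthetic
data therefore demonstrate the correctness of the computational chain — not
that real instrument data satisfies its assumptions; in particular, real
iTRAQ ratios are compressed toward 1 by co-isolation, which widens the
apparent null and makes tier thresholds conservative.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at 500 proteins × 5 experiments
(≈7,000 PSMs), fits 100 replicate calibrations of 370 ratios each, and
cross-checks filtering/aggregation against brute-force reimplementations on
1,000 random records — sizes chosen to exercise every code path at
interactive runtimes while keeping Monte-Carlo standard errors an order of
magnitude below the tolerances asserted. Degenerate inputs are handled
explicitly: all-identical ratios refuse the Gaussian fit; a filter cascade
that removes everything finishes with a warning and a valid manifest;
singular correction matrices and overlapping extraction windows are
configuration errors; ratios at tier boundaries follow the half-open
conventions above; clustering ties break by lowest row index.

## Known limitations

* Protein inference is intentionally trivial (accession-keyed); no
  parsimony grouping, and decoys are excluded rather than used for FDR
  estimation.
* The binomial over-representation test treats class membership as
  independent draws; for large classes relative to the reference this
  slightly misstates the hypergeometric truth (use the Fisher option there).
* Whether the calibration ratio set should be peptide-level or
  protein-level is left to the caller — the fit records `n` and fits
  whatever ratio vector it is given.
* p-values of external over-representation reports are not reproducible
  without knowing the tool's multiplier convention; only expected counts,
  folds and directions are.
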