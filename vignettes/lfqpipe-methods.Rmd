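---
title: "Methods: two-condition LFQ differential abundance with presence/absence detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition LFQ differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpipe)
```

## The problem

Label-free quantification compares protein abundance between conditions
through MS intensity alone, so the data arrive with two awkward properties:
intensities span orders of magnitude with only a handful of biological
replicates per condition (here 2 × 3), and missing values are *not* missing
at random — a protein near the instrument's detection limit drops out of a
run precisely because it is low-abundance (MNAR). A two-stage fruit
development comparison adds a third feature: proteins genuinely expressed in
only one stage, which appear as an all-or-nothing detection pattern rather
than as a measurable fold change. The pipeline treats these three properties
explicitly rather than pretending the data are complete.

## Model and procedure

All computation after parsing happens on the log2 scale; a raw LFQ intensity
of 0 is the missing-value sentinel, and "valid value" means raw intensity
> 0.

**Quality filters.** Reverse-database hits, contaminants and
"only identified by site" entries are removed, and the stringent
identification criterion (≥ 2 razor+unique peptides, ≥ 1 unique) is applied.
Both peptide thresholds are arguments (`min_razor_unique`, `min_unique`), so
the permissive one-peptide identification list is available as
`apply_quality_filters(pg, 1, 0)`.

**Valid-value filter.** A protein is quantifiable when it has valid values
in at least 4 of the 6 samples, *or* in all replicates of one condition and
none of the other. The latter (3:0 / 0:3) proteins are flagged
stage-specific. Note the asymmetry this creates on purpose: (3,1) qualifies
through the ≥ 4 rule and is *not* stage-specific, because one detection in
the other stage falsifies true absence, while (2,1) and sparser patterns are
excluded entirely. The decision table for all 64 patterns is pinned by a
brute-force oracle in the test suite.

**Imputation.** Retained proteins route to exactly one branch:

* *Downshifted normal* (1–2 missing cells in total). Each missing cell in
  sample $s$ is an independent draw from
  $\mathcal N(\bar x_s - d\,\hat\sigma_s, (w\,\hat\sigma_s)^2)$ with
  downshift $d = 1.8$ and width $w = 0.3$. The two constants are unitless
  multiples of the per-sample SD of *observed* log2 intensities — the
  established convention for this imputation, adopted here because the
  parameters are conventionally quoted without units. The rationale of the
  downshift is the MNAR mechanism itself: a missing value was most likely
  low, so fills are centred 1.8 observed-SDs below the sample mean with a
  deliberately narrow spread.
* *Average minimum log-intensity* (condition-absent proteins). All missing
  cells receive one deterministic value, the unweighted mean over all 6
  samples of each sample's minimum observed log2 intensity. This is the
  simplest reading of "across runs"; a per-condition variant (mean of the
  absent condition's minima only) is available via `min_fill =
  "per_condition"` for sensitivity analysis, since the exact convention
  differs between software versions.

Cells are filled in (protein, sample) lexicographic order from a single
seeded stream, so results are reproducible and independent of row storage
order. Observed cells are never modified.

**Testing and classification.** The relative abundance ratio is the
difference in mean log2 intensity (second condition minus first, imputed
values included). The default test is the two-sided Student two-sample
t test (pooled variance, 4 df at 3 + 3) — the convention of the interactive
proteomics environments this pipeline mirrors — with Welch available by
argument. FDR control defaults to Benjamini–Hochberg; a label-permutation
alternative pools |t| over all 10 distinct balanced relabelings of a 3 v 3
design and estimates q as the mean null exceedance count over the observed
exceedance count, with step-up monotonicity enforced. No variance-moderation
("S0"-style) fudge term is implemented: the published description names only
an FDR threshold, and guessing an unstated regularizer would change the
test's null distribution silently.

Categories: stage-specific flags override everything
(MG30-specific / R45-specific); otherwise |ratio| ≥ 0.58 with q < 0.05 gives
MG30-/R45-enriched by sign; |ratio| ≤ 0.58 is invariant; and a large ratio
failing the FDR gate is *putatively-invariant*. Two deliberate conventions:

* The cutoff is **0.58 exactly** — the two-decimal rounding of
  $\log_2 1.5 = 0.58496$ — because that is how the threshold is
  conventionally printed and applied; it is an argument (`logfc_cut`) for
  anyone preferring the unrounded value.
* The quoted interval definitions overlap at exactly ±0.58; the closed
  invariant interval wins there, as the conservative label.
* The five-category scheme folds putatively-invariant proteins into
  "invariant"; the pipeline keeps them as a distinct sixth label so both
  groupings can be reported. End-to-end recovery comparisons in the test
  suite are made on the five-category grouping.

**Over-representation.** One-sided Fisher exact test (upper hypergeometric
tail, $P(X \ge \text{observed})$) of the differential set against the
quantified background, per GO term with ≥ 1 background annotation; fold
enrichment is observed/expected with expected
$= n_\text{query} \cdot K_\text{term} / N_\text{background}$. Correction
defaults to BH across tested terms, with Bonferroni available for
compatibility with classification services that use it. Depletion is not
tested by default (configurable two-sided). Annotations are used exactly as
given — no GO-graph ancestor propagation; a precomputed closure can simply
be supplied in the annotation table.

**Integration.** Transcript log2 ratios come from normalized RPM with a
pseudocount ε (default 1 RPM; ε = 0 drops double-zero genes with a
warning — both zero-handling conventions are plausible and neither is
universal, so both are provided). Pairing is one point per quantified
protein via its gene id, so two protein groups mapping to one gene each
contribute a point, and stage-specific proteins participate with their
imputation-derived ratio. Pearson r with the classical t-based test
(`cor.test` semantics) is reported globally and per functional class with
≥ 3 points.

## The synthetic-data generator

`simulate_lfq()` emulates the study design the analysis assumes: two
conditions × 3 replicates; per-protein baselines $\mathcal N(25, 2^2)$ on
the log2 scale; condition means baseline ± FC/2 with ~10% differential
proteins, |log2 FC| uniform on [0.58, 3]; replicate noise
$\mathcal N(0, 0.25^2)$; logistic dropout on the *true* cell value,
$P(\text{drop}) = 1/(1 + e^{0.8(x - 19)})$, so low-abundance proteins drop
out preferentially — the regime the downshifted imputation presumes. The
midpoint/steepness defaults place the detection limit ≈ 3 SD below the
proteome centre, giving an overall missingness of a few percent with
dropout concentrated in the low-abundance tail, which is the deliberate
design point: sparse enough that most proteins are complete, severe enough
that every imputation branch and the 3:0/0:3 rule are exercised. About 4%
of proteins are made stage-specific by deterministic full dropout in one
condition (with a large planted FC of matching sign), so the
presence/absence branch has exact ground truth. Decoy rows (reverse,
contaminant, site-only, low-evidence) are appended to exercise the quality
filters.

Transcripts are built per functional class by a bivariate construction with
the noise component orthogonalized against the planted protein fold
changes, so the *realized sample correlation equals the class target
exactly*; transcript FCs are drawn with SD equal to the protein-FC SD
divided by the dynamic-range slope (default 0.6), reproducing the wider
dynamic range of transcript changes. Fourteen classes with heterogeneous
targets (from 0.88 down to −0.04) are the default. Three GO terms are
planted at elevated annotation probability among differential proteins.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: shared-peptide/protein-group inference artifacts,
between-sample normalization drift, batch or gel-slice effects, correlated
replicate noise, heavy-tailed intensity error, and annotation errors. The
generator's clean normality is exactly what makes the statistical oracles
sharp; conclusions about robustness to the listed effects need real data.

## Numerical and calibration choices

* Sample statistics use observed values only, SD with the n−1 denominator;
  a sample with < 2 observed values is a hard error, zero SD a warning.
* Degenerate t tests follow a fixed contract: zero pooled variance with
  equal means gives t = 0, p = 1; with unequal means, p = 0 plus a warning.
* FDR calibration is assessed on the t-test's discovery set — q < 0.05
  among non-stage-specific proteins. Condition-absent proteins receive
  three identical min-fill values, so their within-group variance is
  degenerate and their q is an artifact; their category comes from the
  detection pattern, not the test, and counting them as FDR discoveries
  would measure the presence/absence rule instead of the FDR procedure.
  Under repeated null simulations the discovery-set false discovery
  proportion sits at BH's nominal level (the suite checks ≤ 0.075 over 500
  runs of 1000 proteins).
* Problem sizes used by the suite and the acceptance script — 10⁵ draws for
  the imputation distribution check, 500 null simulations and 20 recovery
  runs at 1000 proteins, 50 correlation-recovery seeds at 400 proteins —
  were chosen to keep the Monte-Carlo error of each checked quantity well
  below its assertion margin.

## Known limitations

* **Power at n = 3.** With three replicates per group the t statistic has
  4 df. At a planted |log2 FC| of 1.0 and replicate SD 0.25 the
  noncentrality is ≈ 4.9, and *no* valid per-protein FDR procedure can
  deliver both high sensitivity (≥ 0.9) and strict FDP control (≤ 0.1):
  holding the false discovery proportion at 0.1 forces a |t| cutoff whose
  noncentral tail mass is ≈ 0.5. The acceptance suite measures the
  operating characteristics honestly rather than masking them; sensitivity
  is high only for larger effects (the generator's default effect range) or
  smaller noise. Moderated-variance tests would change this but are out of
  scope by design.
* The t test is slightly anticonservative in the extreme tail for proteins
  near the detection limit, because surviving (complete) observations are
  soft-truncated from below by MNAR dropout; at the default missingness
  level the effect on FDR calibration is within the nominal margin.
* Permutation FDR at 3 v 3 rests on only 10 distinct relabelings, so its
  q-value resolution is coarse; it is offered for fidelity, not precision.
* GO results are only as good as the supplied annotation; no ontology
  structure is used.
* Exactly two conditions are supported; time courses and >2-group designs
  are out of scope.
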