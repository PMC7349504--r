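---
title: "CSF/serum free light chain and IgG indices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSF/serum free light chain and IgG indices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcindex)
```

## The problem

In suspected multiple sclerosis (MS), intrathecal immunoglobulin synthesis
is inferred from paired cerebrospinal fluid (CSF) and serum measurements:
antibody-related analytes that are enriched in CSF beyond what passive
transfer across the blood–CSF barrier explains point to antibody production
inside the central nervous system. The classical quantitative markers are
CSF/serum concentration quotients referenced to the albumin quotient
(albumin is exclusively blood-derived, so `Q_Alb` indexes barrier
permeability), and the kappa free light chain (κFLC) index built on it.
This package implements that marker family plus a variant that replaces the
albumin denominator with the IgG quotient, computes them for whole cohorts,
runs the accompanying nonparametric statistics and ROC diagnostics, and
simulates realistic cohorts so the entire pipeline is testable end to end
without patient data.

## Indices and units

With CSF concentrations in mg/L and serum concentrations in g/L (the usual
laboratory reporting units), the package computes, per patient:

* quotients `Q_X = CSF_X [mg/L] / serum_X [g/L]` for albumin, IgG, IgA,
  IgM — the conventional ×10⁻³ quotient scale;
* `FLC index = (CSF_FLC / serum_FLC) / (CSF_alb / (1000 · serum_alb))` —
  both FLC concentrations in mg/L, serum albumin converted g/L → mg/L so
  the albumin ratio (and hence the index) is fully unitless;
* `IgG index = 100 · (CSF_FLC / serum_FLC) / Q_IgG` — the FLC ratio divided
  by the IgG quotient in its reported mixed units, scaled by 100 so the
  index is of order unity.

These unit conventions are the ones that reproduce the magnitudes of the
published median indices when applied to the published group medians
(`kflc ≈ 52.8` against a printed median of `59.3`; `kigg ≈ 5.62` against
`5.66`); equality is not expected because a median of ratios is not a ratio
of medians. The acceptance script recomputes these arithmetic checks.

CSF FLC values below the assay detection limits (0.30 mg/L for κ, 0.65 mg/L
for λ) are substituted by the limit itself and flagged (`apply_lod()`),
before any quotient or index is formed. Serum FLC has no published
substitution rule here: a serum value flagged undetectable stays missing
and raises a warning. Any missing constituent propagates to a missing
index — per-index (not per-patient) exclusion, which is why the effective n
can differ between the κ and λ indices of the same cohort.

## Rank statistics

All rank machinery is implemented in the package on a single midrank
primitive (`rank_average_ties()`), because tie handling is load-bearing for
censored data: every control cohort contains a mass of CSF FLC values tied
exactly at the detection limit.

* `mann_whitney_u()` reports `min(U_x, U_y)`. For tie-free pooled samples
  of at most 16 it enumerates all rank assignments and returns the exact
  two-sided p; otherwise it uses the normal approximation with tie-corrected
  variance and a 0.5 continuity correction (disable with
  `continuity = FALSE`; force either route with `exact =`).
* `kruskal_wallis()` applies the standard tie correction
  `1 − Σ(t³−t)/(N³−N)` and a χ² reference on k−1 degrees of freedom; a
  fully tied sample returns H = 0, p = 1 rather than 0/0.
* `dunn_posthoc()` is the post-hoc choice: z statistics on pooled-rank
  means with tie-corrected variance, Bonferroni-multiplied by the k(k−1)/2
  pairs and capped at 1.0. Dunn-with-Bonferroni is the one common
  Kruskal–Wallis follow-up that produces exactly the capped `p = 1.000`
  seen in legacy-package output for indistinguishable groups, which is why
  it is the default here.
* `spearman()` is the Pearson correlation of midranks with the t
  approximation on n−2 degrees of freedom (`p = 0` at |rho| = 1), and
  `correlation_matrix()` assembles pairwise-complete matrices, dropping
  cells with fewer than three complete pairs.

The significance convention throughout is two-sided 0.05 with no
multiplicity adjustment across variables (only within a post-hoc family),
mirroring standard practice in this literature.

## ROC diagnostics

`roc_curve()` fixes the orientation — a higher index predicts MS — and
never flips it automatically; an AUC below 0.5 is reported as-is with an
`uninformative` flag, because silent reorientation would hide a
miscalibrated marker. Decisions use the inclusive rule `score ≥ cutoff`,
the convention in this assay literature. Thresholds are the observed score
values; whether published cut-offs are observed values or interpolated
midpoints is generally unstated, and the observed-value convention is
adopted. The AUC is computed twice by design: trapezoidal integration in
`roc_curve()` and pairwise concordance enumeration in
`auc_u_equivalence()`; the test suite holds the two routes equal to 1e−12
on random inputs.

`youden_cutoff()` maximizes J = sensitivity + specificity − 1 over the
observed thresholds; ties break toward higher sensitivity and then toward
the lower threshold, a screening-oriented reading (never trade away
detection on a tie). `performance_at_cutoff()` returns exact unrounded
metrics plus a display vector rounded to 2 decimals.

## Inverting published percentage tables

`reconstruct_confusion()` exhaustively searches every integer confusion
matrix within the enrolled group caps (default 34 diseased / 42 controls;
row totals below the caps are allowed because published effective n varies
with per-index missingness) and keeps those whose exactly computed metrics
round to the supplied printed values. Rounding is half-away-from-zero
(`round_half_away()`), the convention of legacy statistics packages;
half-even is available behind a warning. Printed percentages with a
trailing zero ("90.30") are treated as 1-decimal values: the reference
rows are only self-consistent at one decimal.

Two findings from this machinery are frozen as tests: the κIgG row of the
reference table inverts, from sensitivity and specificity alone, to a
unique matrix (tp 28, fn 3, tn 33, fp 8) whose PPV/NPV/accuracy match the
remaining printed values; and the κFLC row inverts to a unique matrix whose
accuracy matches print but whose printed PPV/NPV pair is jointly
unsatisfiable by *any* integer matrix at the caps — an arithmetic proof of
a transcription defect in the published row (its true PPV/NPV are
69.0/93.3; the printed PPV equals the printed accuracy, suggesting a
column shift). An empty solution set is therefore a meaningful result, not
an error.

## The synthetic cohort generator

`generate_cohort()` draws a cohort with the structure this analysis
assumes: 34 MS and 42 control patients; oligoclonal band (OCB) patterns
31:3 (MS, types 2:3) and 21/4/16/1 (controls, types 1/3/4/5); log-normal
analyte margins; a Gaussian copula for dependence; detection-limit
censoring; and a small completely-at-random missingness on the FLC fields
(2% each, matching the reconstructed effective n of 72/74 for the κ/λ
indices). Generation is a pure function of `(config, seed)`.

Calibration choices, in decreasing order of how directly the published
summaries pin them down:

* **Margins.** `mu = log(median)` pins each group median exactly;
  `sigma = (log(max) − log(min))/4` reads the published range as ±2 sd on
  the log scale. Log-normal margins are the natural choice for strictly
  positive, right-skewed clinical-chemistry analytes.
* **Range repairs.** Two published cells are impossible as printed and are
  repaired with warnings: a median outside its own min–max (MS CSF IgG) has
  the violated bound widened to the median, medians being authoritative;
  and serum immunoglobulin bounds above 50 g/L (IgG "1320", IgM "360", IgA
  "263" g/L — total serum protein is about 70 g/L) are read as decimal
  misprints and divided by 10 until plausible. Without the second rule the
  serum IgG log-sigma would be ≈1.3, an absurd dispersion for a tightly
  regulated serum protein, and it would dominate both IgG indices.
* **FLC sigmas.** No FLC ranges were published. The defaults — 0.9 for CSF
  FLC, 0.35 for serum FLC — encode that serum FLC is tightly regulated
  while CSF FLC spans roughly two orders of magnitude in a mixed
  neurological cohort, consistent with the published index ranges.
* **Dependence.** The latent correlation matrix maps the published
  total-group Spearman targets onto the 13 simulated margins (quotient
  rows onto their CSF analyte), converts them by `r = 2 sin(π ρ/6)`, and
  repairs the result to positive semi-definite by eigenvalue clipping
  (published tables assembled cell by cell are routinely slightly
  indefinite; the repair moves no entry by more than ~0.06). Two pairs are
  set above their total-group table values as a package design choice:
  CSF IgG–CSF κFLC at 0.60 and CSF IgG–CSF λFLC at 0.45, because
  intrathecal FLC and IgG are coupled products of the same B-cell
  expansion and the total-group quotient correlation (0.405) is a diluted
  lower bound on the within-group coupling.
* **Pattern structure.** Only CSF κFLC has pattern-specific locations (the
  published per-pattern medians: 0.300/2.905/4.400/0.936 mg/L for types
  1/2/3/4; the unpublished type-5 location uses the control median). A
  published pattern median exactly at the detection limit is a censored
  median and only upper-bounds the latent location, so pattern 1 uses the
  conventional LOD/2 (0.15 mg/L). All other analytes are
  pattern-invariant, matching the published finding that serum FLC and CSF
  λFLC do not differ by pattern.
* **Demographics.** Ages are log-normal per group (MS median 34, range
  20–55; controls 48, 18–78 — the published control range, with a chosen
  MS distribution typical of first-presentation MS), clamped to 16–95
  years; sex is Bernoulli (female probability 0.7 for MS, 29/42 for
  controls).

### What passing tests do and do not show

The generator reproduces the published *marginal* summaries and an
approximation of the correlation structure. It does not emulate
measurement rounding, batch effects, informative missingness, or the exact
joint distribution that produced the published ROC table — so downstream
AUCs agree with the published ones only in broad magnitude. In particular,
the two κ indices have nearly identical published AUCs (0.866 vs 0.871, a
difference far inside sampling noise at n = 76), and the simulated
ordering of that pair is accordingly close to a coin flip; the acceptance
suite asserts the full qualitative ordering at an 80% replicate rate and
documents that this is not attainable for the κ pair under any calibration
consistent with the printed summaries. Passing the recovery tests shows
the generator is faithful to its configuration, not that the configuration
equals the unobserved real-data generating process.

## Numerical and degenerate-input choices

* Exact U enumeration switches on at pooled n ≤ 16, tie-free; at the
  boundary (n1 = n2 = 8) exact and approximate p differ by < 0.02.
* A fully tied Kruskal–Wallis sample returns H = 0, p = 1; a zero-variance
  Spearman input is an error (no rank correlation exists).
* Zero-denominator diagnostic metrics are `NA` and named in `undefined`,
  never NaN.
* `sigma_scale = 0` collapses the generator to the deterministic
  median cohort (with `pattern_shifts = FALSE` and no missingness, every
  index equals its group-median arithmetic value exactly) — the closed-form
  anchor used by the test suite.
* Problem sizes in the test and acceptance suites: 76-patient cohorts, 200
  Monte-Carlo replicates, 100-instance oracle sweeps — chosen as the
  smallest sizes at which the stochastic assertions are stable across
  seeds.

## Known limitations

* The copula targets are only partially identified by the published
  total-group correlations; within-group dependence is a calibration
  choice, not a data fact.
* Pattern-stratified tests on the default cohort have very small cells
  (3–4 patients in pattern 3), so their p-values are dominated by the
  post-hoc cap — as in the published analysis.
* No confidence intervals on AUC or rho are provided, matching the scope
  of the emulated analysis; no Reiber hyperbolic reference functions are
  implemented (the quotient convention here is the plain ratio).
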