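---
title: "Models and methods behind ernscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ernscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernscreen)
library(dplyr)
```

# The assay and its statistical model

`ernscreen` analyses arrayed CRISPR knockout fitness screens in which each
well of a multi-well plate holds a cell population carrying one gene
knockout, and the endpoint readout is a cell count per well. The design it
targets is a library of epigenetic regulator genes arranged on edge-excluded
96-well plates: only the interior 6 × 10 block (rows B–G, columns 2–11) is
used, because evaporation and temperature gradients make the outer ring
unreliable. Each plate carries 50 target genes plus 10 wells of a
non-expressed negative-control gene (*TNP2* by default), and each condition
is measured in 3 replicates.

## Fitness scores

The per-gene fitness score is

$$s_{g} = \log_2 \frac{n_{g}}{\bar n_{\mathrm{ctrl}}},$$

where \(n_g\) is the knockout well's cell count and
\(\bar n_{\mathrm{ctrl}}\) the arithmetic mean of the raw counts in the
same plate's negative-control wells, within the same condition and
replicate. Scores are computed per replicate and averaged (mean ± SEM),
so replicate-level variability is preserved. Because numerator and
denominator share the plate, any multiplicative plate effect cancels
exactly — the test suite asserts this invariance under arbitrary per-plate
scalings.

Two normalizations coexist deliberately and are **not** unified:

* fitness scores divide by the mean of the *raw* control counts;
* the interaction model (below) subtracts the mean of the
  *log2-transformed* control counts as a regression offset.

The two differ by Jensen's inequality; each matches the convention of its
downstream analysis, and collapsing them would silently change one of the
two statistics.

## Dispensability classification

Genes partition into three tiers from their mean score in a condition:

* **fully dispensable** — score inside the *closed* observed range of
  negative-control scores ("within the observed range" includes the
  endpoints);
* **indispensable** — score *strictly* below the half-maximal-effect
  threshold ("stronger than" is strict, so a score exactly at the
  threshold is not indispensable);
* **partially dispensable** — everything between.

The half-maximal threshold defaults to half the minimum mean target score,
capped at 0 (a screen with no deleterious knockout cannot declare anything
indispensable). This min/2 rule is this package's documented
interpretation of "half-maximal effect"; it is override-able with a fixed
value via `half_maximal_threshold(scores, override = )`, which is the
right choice when the most extreme populations trend toward complete
eradication and the observed minimum under-states the true maximal effect
(a fixed threshold of −1 is the convention we mirror for such lines).
`classify_dispensability()` refuses configurations where the half-maximal
threshold does not lie below the control-range minimum, because the two
regimes would otherwise overlap and the partition would be ill-defined.

## Genetic-interaction detection

To ask whether a knockout is *more* deleterious in a sensitized background
(a second knockout, or an oncogene-transformed derivative) than in the
reference background, each gene is fitted independently with the offset
linear model

$$\log_2 n_{gij} - o_{p(g)j} = \mu_g + \beta_g \,\mathbb 1[\text{condition}_j = \text{test}] + \varepsilon_{gij},$$

where \(o_{pj}\) is the mean log2 negative-control count of plate \(p\) in
the same condition and replicate. The condition coefficient \(\beta_g\) is
the interaction effect on the log2 scale, tested two-sided by a Wald test.
A gene is called an interactor iff \(P < 10^{-3}\) **and**
\(|\beta_g| > 0.2\), both strict; no multiple-testing correction is
applied, matching the raw-P dual-threshold convention of this assay class.
The log base is 2 throughout, so the 0.2 threshold lives on the same scale
as the fitness scores.

### Choice of the Wald reference distribution

With 3 replicates per condition the model has 4 residual degrees of
freedom, and the choice of reference distribution is material.
`fit_interaction_model()` defaults to the exact-under-Gaussian t reference
with \(n-2\) df and offers `wald = "normal"` for the asymptotic
convention. The package's own calibration analysis (reproduced by the test
suite and the acceptance script) drives the default:

* under the t reference, the realized null interactor rate at
  \(P < 10^{-3}\) with the coefficient filter is below the nominal level
  (≈ 2–5 × 10⁻⁴ at σ = 0.1), as it should be;
* under the normal reference the same screen shows a ≈ 5-fold inflated
  null rate (≈ 5 × 10⁻³), because a t(4) statistic referred to a normal is
  strongly anti-conservative.

The flip side is power. For a planted effect of −0.6 at replicate noise
σ = 0.15 with 3 + 3 observations, the noncentral-t power of the strict
dual criterion is ≈ 0.15 under the t reference and ≈ 0.87 under the
normal one — and even an oracle z-test with *known* variance caps at
\(P(|N(4.90, 1)| > 3.29) \approx 0.946\). Near-complete recall at these
settings is therefore not achievable by any Wald-type variant; detecting
such effects reliably at \(P<10^{-3}\) requires either more replicates or
pooling information across genes. We keep the calibrated t default and
report measured recall rather than trade type-I control for sensitivity.

A degenerate fit (zero residual variance with a nonzero coefficient, as
happens on noiseless synthetic data) reports P at the reference
distribution's lower limit and sets a `degenerate` flag; all-identical
input returns coefficient 0 with P = 1.

### Transformation-context classes

Comparing interactor calls between an untransformed and a transformed
background, genes are labelled `unique` (significant only upon
transformation), `enhanced` (significant in both with a more-negative
transformed coefficient), `shared_unchanged`, or `none`. The
`enhanced`-vs-`unique` boundary compares point estimates; this is the
package's documented interpretation, since no significance test on the
coefficient *difference* is implied by the dual-threshold calling rule.
Genes significant only in the untransformed background are flagged
separately rather than given a class of their own.

## Enrichment statistics

`class_enrichment()` runs one global χ² test of homogeneity on the
(status × functional class) contingency table — df = classes − 1, hence
7 df for the eight-class library — plus per-class
\(\log_2(\text{observed}/\text{expected})\) ratios. Because expected
counts are proportional to class sizes, the ratio is identical whether
computed on proportions or raw counts, so the single computation serves
both conventions. `paralogue_enrichment()` applies the analogous 2 × 2
analysis for paralogue status; no continuity correction is applied by
default (a plain two-tailed χ² is the convention mirrored here), with a
Yates-corrected variant behind `yates = TRUE`. A group with zero observed
genes would have a ratio of −∞; it is reported as missing with a
`depleted_to_zero` flag instead. Cross-line concordance uses the Pearson
correlation of mean scores and the overlap of *dispensable* sets, where
"dispensable" means not-indispensable (fully + partially), measured
against the query line's dispensable set.

# Histone-PTM quantification

Input begins at integrated chromatographic areas per modification form of
each peptide, in a light (sample) and heavy (spiked-in labelled internal
standard) channel. Percent relative abundance is

$$\%RA_f = 100 \cdot \frac{A_f}{\sum_{f'} A_{f'}},$$

summing over all observed forms of the peptide within one channel and
replicate; the standard-referenced quantity is the ratio
\(L/H = \%RA_L / \%RA_H\). Differential calling expresses per-replicate
\(\log_2(L/H)\) relative to the mean of the reference sample and tests
each form with a two-sided two-sample t-test (pooled by default, Welch
optional). A form is changed iff its mean log2 fold change leaves the
interval (−0.41, 0.58) *and* P < 0.01, all strict. The asymmetric
interval is kept as printed in the convention we follow — its gloss is a
1.5-fold change, and indeed \(\log_2 1.5 = 0.585 \approx 0.58\), but the
lower bound −0.41 is not \(-\log_2 1.5\); we deliberately do not
"correct" it, and both bounds are configurable. Undetected forms (zero
area in any replicate of either sample) propagate as missing values
end-to-end — never as zeros, which would fabricate infinite fold changes.

## The peptide-area generator and compositionality

%RA is compositional: multiplying one form's area changes every form's
%RA through the denominator. A generator that planted fold changes that
way would never reproduce them exactly downstream. `simulate_peptide_areas()`
instead models modification-state *interconversion*: a planted fold on a
form shifts abundance between that form and a designated balance form
(default `"unmod"`, else the largest untouched form), conserving the
peptide's total abundance. Under zero noise the recomputed log2 L/H ratio
relative to the reference then equals \(\log_2(\text{fold})\) exactly,
which the tests assert to machine precision. Folds that would drive the
balance form negative are rejected. Noise is multiplicative lognormal per
area with unit mean, parameterized by a coefficient of variation.

# Auxiliary quantification rules

**Immunofluorescence knockout gate.** Edited cells are those with
intensity *strictly below the median* of the control population. Note an
intrinsic property of this gate: escape cells are distributed like the
control, so half of them also fall below the control median, and against
a population with edited fraction \(f\) the gate returns
\(f + (1-f)/2\), not \(f\) — 0.85 for a 70 %-edited population. The tests
assert this analytic value and show that \(2g - 1\) debiases the gate;
the gate itself is kept as defined because it is the field's convention
and is monotone in \(f\).

**Clone scoring.** A candidate double-knockout clone is scored KO when its
mean signal lies within k SD (closed interval, default k = 2) of a
reference population in which the mark is fully depleted
pharmacologically. With zero reference SD only exact equality passes,
with a warning.

**Growth-rate comparison.** Per replicate, the least-squares slope of
log2 signal against time restricted to a closed window (default 24–48 h,
the exponential phase between seeding recovery and confluence); the two
conditions' slope sets are compared by a two-sided two-sample t-test.
Zero slope variance in both groups is degenerate: equal means give
t = 0, P = 1; unequal means are flagged with a missing P rather than a
fabricated zero.

**Peak filtering.** Intervals are 0-based half-open internally (BED
convention; `one_based = TRUE` converts at the boundary).
`consensus_peaks()` keeps regions with fold change ≥ 5 (inclusive)
supported by ≥ 1 bp overlap in *every* replicate, reporting the union of
the overlapping replicate intervals; the result is invariant to replicate
order and idempotent. The 1-bp presence rule is the permissive reading of
"present in all replicates"; a minimum-overlap option exists.
`differential_peaks()` retains peaks with log2 concentration ≥ 5 in at
least one condition and labels a retained peak differential iff
\(|\log_2 FC| \ge 1\) (inclusive) and FDR < 10⁻⁴ (strict); the unaffected
fraction is 1 − differential/retained. FDR is expected from the upstream
differential-binding tool; when derived internally (opt-in) it is
Benjamini–Hochberg.

# The synthetic-data generator

`simulate_screen()` draws
\(n = 2^{b_p + e_g + i_{gc} + \varepsilon}\), with a per-plate log2
baseline \(b_p\) (default 10, ≈ 1000 cells/well at endpoint), per-gene
fitness effect \(e_g\), per-(gene, condition) interaction effect
\(i_{gc}\), and \(\varepsilon \sim N(0, \sigma)\) on the log2 scale —
i.e. multiplicative noise on counts, matching the
log-transform-then-linear-model analysis. The default replicate noise
σ = 0.15 was chosen once as representative of well-level count
variability in arrayed endpoint screens (replicate SEMs of a few tenths
on the log2 scale). Counts stay real-valued by default so that noiseless
runs recover the planted truth exactly; `integer_counts = TRUE` adds
rounding for realism. The shared per-plate baseline is exactly the
systematic effect the negative-control normalization must remove, and
tests verify that it does.

`simulate_true_effects()` defaults to a landscape in which 12 % of
targets carry strong effects (uniform on −3…−1 log2), 20 % mild effects
(−0.6…−0.15), and the rest are neutral — the shape seen in regulator
screens of normal somatic cells, where most single knockouts are
tolerated. The knockout-escape fraction (default 0.3, i.e. ~70 % edited
cells) parameterizes the intensity-mixture generator and an optional
effect-attenuation switch in `simulate_screen()`
(`apply_ko_escape = TRUE`, off by default): the stated count model has no
escape term, and keeping it out of the default path preserves the exact
noiseless-recovery property that anchors the test suite.

What the generator does **not** emulate: spatial within-plate gradients
beyond the excluded edge ring, guide-level editing heterogeneity,
replicate-correlated batch effects, or count discreteness (by default).
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not robustness to artifacts
the model excludes; on real data, plate-edge QC and editing validation
remain the analyst's responsibility.

# Numerical choices and problem sizes

* Degenerate interaction fits are detected by comparing the residual sum
  of squares against the data's scale (relative tolerance 10⁻²⁴),
  preventing floating-point residue in constant input from fabricating
  test statistics.
* %RA conservation is asserted to 10⁻⁹; noiseless round-trips to
  ≤ 10⁻¹⁰; oracle equivalence between the model fit and the closed-form
  pooled-t computation to 10⁻¹⁰ over randomized instances.
* Boundary conventions are pinned by dedicated tests: closed control
  range, strict half-max, strict dual interaction thresholds, closed
  clone gate, inclusive fold ≥ 5, inclusive \(|\log_2 FC| \ge 1\), strict
  FDR < 10⁻⁴, strict PTM interval.
* Simulation sizes used by the suites — 2000 null genes for type-I
  calibration, 500 genes for effect recovery, 10⁵ cells for gate
  accuracy, 1000 random peptide groups for conservation — were chosen as
  the smallest sizes at which the binomial/Monte-Carlo error is an order
  of magnitude below the asserted tolerances.
* All generators take explicit seeds and are byte-reproducible given
  seed + configuration.

# Known limitations

* The min/2 half-maximal rule ties the indispensability threshold to the
  single most extreme knockout; with small libraries this is noisy, and
  the override exists for exactly that reason.
* The per-gene model treats replicates as independent; plate-level noise
  shared between genes is removed only through the offset term, so
  residual co-variation between genes on one plate is not modelled.
* Near-complete recall of −0.6 log2 interaction effects at σ = 0.15 with
  3 replicates is information-theoretically out of reach at the strict
  P < 10⁻³ criterion (see the Wald-reference discussion); interpret
  recall figures accordingly.
* The enzyme-low gate over-counts by construction (above); comparisons
  between populations gated the same way remain valid.
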