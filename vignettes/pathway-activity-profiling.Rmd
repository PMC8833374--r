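---
title: "Bayesian-network pathway activity profiling of CD4+ T cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-network pathway activity profiling of CD4+ T cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpscore)
```

## The problem

The functional state of a CD4+ T cell — resting, immune-activated, Th1/Th2
polarized, or converted to an immunosuppressive regulatory (Treg)
phenotype — is governed by a small number of signal transduction pathways:
PI3K (read out through its FOXO transcription factor), NFκB, JAK-STAT1/2,
JAK-STAT3, TGFβ, and Notch.  Each pathway's activity can be inferred from
the mRNA levels of a small set (typically 20–30) of direct target genes of
the pathway-associated transcription factor.  `stpscore` implements that
inference as a calibrate-then-freeze Bayesian network, together with the
surrounding workflow: per-sample array quality control, normal-range
thresholding against healthy references, exact small-sample nonparametric
comparisons, and matching of sample profiles to reference immune cell
subsets.

## The scoring model

The network has two layers: a hidden binary pathway state $A \in
\{\text{active}, \text{inactive}\}$ and, conditionally independent given
$A$, one binary evidence node per target gene.  Gene $g$'s evidence is
$e_g = [x_g > c_g]$, where $x_g$ is the log2 expression value and $c_g$ a
per-gene discretization cutoff.  Scoring a sample is a product of
likelihood ratios:

$$\mathrm{odds}(A \mid e) \;=\;
  \frac{P(A)}{1 - P(A)} \prod_g \mathrm{LR}_g(e_g), \qquad
  \mathrm{LR}_g(\text{high}) =
  \frac{P(e_g = 1 \mid \text{active})}{P(e_g = 1 \mid \text{inactive})},$$

reported as the **log2 odds** $\log_2 \mathrm{odds}(A \mid e)$, the unit
used throughout.  Probe-summarized input makes a separate probeset layer
unnecessary; discretization absorbs it.

Calibration estimates, per gene, the cutoff $c_g$ as the **median of the
gene's values over all training samples** (both classes pooled) and the
two conditional probabilities as Laplace-smoothed frequencies of
$x_g > c_g$ within each class (pseudocount 1 by default, so every
probability is strictly inside $(0,1)$ and no likelihood ratio is ever 0
or infinite).  The model is then **frozen**: it is applied to any new
sample without adaptation, which is what makes scores comparable across
cohorts.  Down-regulated target genes need no special code path — their
`p_high_given_active` simply calibrates below `p_high_given_inactive`.

Numerical choices:

* `prior_active = 0.5` (log2 prior odds 0).  No informative prior is
  available, and interpretation rules below do not read the sign of a
  score as "active/inactive" anyway.
* Log2 odds are clamped to $[-60, 60]$.  Beyond $|{\sim}25|$ the paired
  probability is no longer distinguishable from 0/1 in double precision,
  so the probability/odds identity
  $\text{log2 odds} = \log_2 P - \log_2 (1-P)$ is only asserted away from
  the clamp.
* Genes absent from a sample contribute $\mathrm{LR} = 1$ and are listed
  in `missing_genes`; a sample sharing *no* genes with the model is an
  error, never a silent prior return.
* `score_sample_enumeration()` recomputes the posterior by brute-force
  enumeration of the full joint table; it is the validation oracle for the
  factorized implementation (agreement to $< 10^{-9}$ on random models).

Interpretation rules enforced structurally rather than numerically: raw
log2-odds scores are never pooled across pathways into one statistic (each
pathway has its own dynamic range); FOXO is always reported as FOXO
transcription-factor activity, with PI3K inferred only qualitatively and
inversely via `infer_pi3k_from_foxo()`, and only in the absence of
oxidative stress; a negative score is not reported as "pathway inactive".

### Why calibration uses a dedicated active/inactive cohort

Frozen models for all six pathways need a calibration contrast for each
pathway.  The resting-vs-activated condition provides none for Notch
(activation leaves Notch essentially unchanged in the anchor profiles), so
`calibrate_preset_models()` simulates a dedicated two-class calibration
cohort — every pathway fully active vs fully inactive, one cell-type
population — calibrates each model there, and freezes it.  This mirrors
the calibrate-on-one-cell-type-then-freeze protocol and keeps every model
estimable from a single designed contrast.

## Sample quality control

QC consumes a per-sample metrics table (probe-level CEL processing is out
of scope; calculators are provided for the metrics derivable from probe
summaries, `three_prime_ratio()` and `rna_degradation_slope()`).  The rule
engine is a pure function of (metrics, rules): rule order is irrelevant, a
sample passes iff every enabled rule passes, and failures name their rule.
The default panel has 11 rules — average intensity, negative-value and
>16-bit overflow counts, poly-A and cRNA spike-in flags, GAPDH and ACTB
3′/5′ ratios, center of intensity, positive/negative border means, RNA
degradation slope.  Published Affymetrix guidance pins only the ratio
bound (3′/5′ ≤ 3) and the zero-tolerance counts; the remaining numeric
bounds have pragmatic log2-scale defaults and are expected to be
overridden per cohort (`cohort_qc_rules()` sets them to cohort mean ± 3
SD).  The full enumeration of the panel differs between published
descriptions, so the rule set is deliberately configurable rather than
hard-coded to a count.

## Statistics

* `mann_whitney()`: mid-rank U; **exact** p (permutation null) when
  $n_1 + n_2 \le 20$ and the pooled values are tie-free, otherwise normal
  approximation with continuity correction.  The sidedness is always
  explicit — the published subtype comparisons are consistent with the
  one-sided exact tail ($U = 3$, $p = 7/252 \approx 0.028$ for groups of
  5 and 5), and the package never guesses a global convention.
* `wilcoxon_paired()`: signed-rank W for within-patient comparisons;
  zero differences dropped (count messaged), exact when $n \le 15$ with
  tie-free $|d|$; an all-zero difference vector degenerates to $p = 1$
  with a warning.
* `pearson_cor()`: two-sided t-transform test, for pathway–pathway
  correlation across samples.
* No multiple-testing correction enters any verdict; a Bonferroni column
  is emitted in comparison tables for transparency only.
* P-values are kept at full precision; rounding (3 decimals) happens only
  at report rendering.

The exact branches are validated in the test suite against independent
brute-force enumeration (all $\binom{n_1+n_2}{n_1}$ labelings; all $2^n$
sign patterns).

## Normal-range thresholds and classification

The upper bound of the normal range is $\bar{x} + 2s$ over healthy
reference scores, with $s$ the $n-1$ sample SD (`normal_threshold()`, at
least two finite references required).  "Mean ± 2SD" is read as an
*upper* threshold because that is how it is used: flagging abnormally
*high* activity.  `classify_abnormal()` uses a strict inequality (a score
exactly at the threshold is normal).  Under a Gaussian reference the
expected false-positive rate is $1 - \Phi(2) \approx 2.28\%$; the
acceptance suite verifies the empirical rate at $n = 10{,}000$ falls in
the 99% binomial interval around that value.

## Profile matching

`match_profile()` compares a sample's six-pathway profile to labeled
reference profiles.  Because raw scores are not comparable across
pathways, each pathway is standardized (centered/scaled) with the mean and
SD of that pathway across the pooled reference set, the sample transformed
identically, and similarity taken as the Pearson correlation of the
standardized vectors.  Ranking is deterministic, with ties broken by
reference label order.

## The synthetic-cohort generator

No real expression data ships with the package; every stage is exercised
on a generator with planted ground truth.  The generative model is
deliberately the simplest one whose truth the score should recover —
linear in activation with Gaussian noise:

$$x_{gs} = \mu_g + d_g \,\Delta\, a_{P(g),s} + \varepsilon_{gs},
  \qquad \varepsilon_{gs} \sim N(0, \sigma^2),$$

with per-gene baselines $\mu_g \sim N(7, 1)$ log2 units drawn once,
direction $d_g = \pm 1$, effect size $\Delta$ and noise $\sigma$ as
user-visible knobs, and background genes carrying no signal.  Defaults:
$\Delta = 2$ log2 units (a strong but realistic array effect), $\sigma =
0.5$ for the preset cohorts and $\sigma = 1$ for calibration and recovery
experiments, 25 genes per pathway, 6 samples per scenario.  R's default
Mersenne-Twister stream under a caller-supplied seed makes every output
bit-reproducible, and the generator restores the caller's RNG state.

The scenario presets encode the study conditions as per-pathway activation
levels $a \in [0,1]$ whose *orderings* reproduce the qualitative anchors
of the in vitro subset experiments (activation raises NFκB/JAK-STATs and
lowers FOXO and TGFβ; Th1 exceeds Th2 in NFκB and JAK-STAT1/2 while Th2
keeps higher FOXO; iTreg combines high NFκB, JAK-STAT3, TGFβ and Notch
with reduced JAK-STAT1/2; supernatant treatment reverts activation while
raising TGFβ and FOXO).  The patient compartments are mixtures of a
healthy-blood background with an iTreg component (Treg fraction 0.25 in
blood, 0.45 in lymph node, 0.85 in tumor infiltrate) — the fractions are
illustrative, chosen once so blood shows attenuated and TIL pronounced
iTreg signatures; their true magnitudes are not quantified anywhere.  The
absolute preset levels themselves are likewise the package's own choices;
only their orderings are anchored.

What the generator does **not** emulate: probe-level array structure,
batch and lab effects, cross-pathway transcriptional crosstalk
(overlapping gene sets are rejected), heavy-tailed noise, and the
cell-type-specific dynamic ranges of the real assay.  Passing tests
therefore demonstrate correctness of the inference machinery on data
matching its assumptions, not the numerical behavior of proprietary
models on real arrays — which is also why the published absolute scores
are used only as *inputs* to the statistical stages, never as targets to
reproduce.

### Discreteness and ties

A binary-evidence model takes scores on a lattice: genes sharing identical
calibrated counts have identical likelihood ratios, and samples whose
evidence differs only by swaps inside such a class score identically.
With a small calibration cohort this produces frequent within-group ties,
which pushes the rank-sum test onto its normal-approximation branch.  The
separated-cohort demonstration (ten high-Notch patients vs four donors,
expected exact two-sided $p = 2/1001 \approx 0.002$) therefore uses a
richer design: 40 Notch target genes calibrated on 100 samples per class
at $\sigma = 1.5$, which makes the per-gene likelihood ratios effectively
unique and the resulting scores tie-free while keeping them inside the
±60 clamp; a=0.85 vs 0.15 guarantees complete separation.

## Problem sizes

The shipped analysis and acceptance runs use: a 66-sample, 250-gene preset
cohort (11 scenarios × 6 samples, 150 target + 100 background genes); a
40-sample calibration cohort per model; 100 random ≤8-gene models for the
enumeration-oracle check; a 100-sample recovery cohort (Δ = 2, σ = 1, 25
genes, 50/50) for the AUC ≥ 0.95 check; and 10,000 reference plus 10,000
new draws for the threshold calibration check.  These sizes were chosen so
the entire suite runs comfortably on a laptop while keeping every check
statistically meaningful.

## Known limitations

* The scoring model is a faithful implementation of the stated concept,
  not a byte-compatible clone of the proprietary assay: the original
  target-gene lists, priors, and probe-level calibrations are not public,
  so absolute score values are not comparable.
* Binary discretization at the training median is the simplest frozen
  rule; continuous or multi-level discretization is out of scope.
* The PI3K readout is qualitative only (`pi3k_low` / `pi3k_high` /
  `indeterminate` relative to a reference FOXO score); whether a
  quantitative inversion is appropriate is left open.
* QC consumes summary metrics, not CEL files; metrics that require
  probe-level parsing must be computed upstream.
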