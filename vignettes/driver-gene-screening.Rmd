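---
title: "Integrative driver-gene screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative driver-gene screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgscreen)
```

# The screening model

A driver gene in a tumor cohort should leave several independent marks at
once: its locus is recurrently gained or lost across patients, its
expression follows its copy number, its expression predicts overall
survival, and knocking it down selectively hurts cell lines from the
tumor's lineage. `dgscreen` implements each of these as a separate
evidence layer over shared data containers and intersects them into one
ranked candidate table. Because real multi-omic cohorts are large,
access-restricted and noisy, the package ships a planted-truth simulator
that emulates the statistical structure of such a study (an aCGH-style
marker grid, a small reference-normal panel, a pooled shRNA screen with a
small target-lineage subset, month-resolution survival) so that every
stage can be calibrated and tested end to end against known answers.

## Recurrent copy-number alterations

Copy number enters as marker-level log2 ratios against a diploid
reference (segmented profiles are expanded back onto the grid, each
marker taking its covering segment's mean; markers covered by no segment
are imputed neutral rather than dropped, keeping the matrix
rectangular). Gains and losses are called at **±0.1 log2, boundary
inclusive** — the conventional any-aberration threshold for this array
class — and a marker's cohort frequency counts samples aberrant in either
direction.

Recurrence is scored per marker and direction with a G score, the
cohort-mean amplitude in excess of the calling threshold:

$$G_{\mathrm{amp}}(m) = \frac{1}{N}\sum_{i=1}^{N} \max(0,\; x_{mi} - \theta_{\mathrm{gain}}),$$

and symmetrically for deletions. This is the standard
frequency-times-average-excess form of recurrence scoring: a region
scores highly only if many samples exceed the threshold by a sizeable
amplitude. Significance comes from a permutation null that permutes each
sample's marker values independently — destroying spatial clustering
while preserving every sample's amplitude distribution — with all
`B × n_markers` null scores pooled per direction, an add-one pseudocount
p-value, and Benjamini–Hochberg q-values within direction. Contiguous
runs of markers with q below the FDR cutoff (default **0.25**) become
peaks; the peak marker is the G-score argmax (leftmost on ties), the
reported frequency is the run maximum, and genes are assigned by
coordinate overlap. We deliberately emit one peak per contiguous
significant run: peel-off refinement and confidence-interval wide peaks
add machinery aimed at resolving co-amplified neighbours, which the
desk-scale simulated cohorts cannot distinguish anyway; the limitation is
that two true drivers inside one uninterrupted significant run are
reported as a single region. Arm-level events are summarised separately:
a sample carries one when strictly more than half of the arm's markers
share the direction's call.

## Copy-number/expression concordance

The integrative step asks, gene by gene, whether copy number and
expression are *equally directed abnormal*: both shifted away from their
reference baselines, in the same direction. Expression is reduced to
per-tumor log2 ratios against the mean of the designated reference
normals; gene-level copy number is the mean of the markers the gene
spans (nearest marker as fallback on sparse grids). Each layer is tested
across tumors with a **one-sample Wilcoxon signed-rank test against
zero**, and concordance requires both p-values below **1e-6** plus
agreeing nonzero directions, where the copy-number direction is the
median's sign only when its magnitude reaches the ±0.1 calling threshold
(expression direction carries no magnitude gate — the array intensity
scale has no natural one).

Two numerical choices matter here. First, the 1e-6 threshold is only
meaningful if the test can actually reach it: the exact signed-rank
floor is $2 \cdot 2^{-n}$, so at least 21 informative tumors are needed,
and a normal approximation in the far tail would be off by orders of
magnitude. The exact null is therefore computed by the shift-algorithm
convolution (each absolute value contributes its doubled midrank with a
fair sign), which handles ties exactly and costs $O(n^3)$ — comfortably
fast up to the default exactness cutover of n = 100, past typical cohort
sizes; beyond that the normal approximation with continuity and tie
correction takes over, and the two paths agree to within 0.01 in p at
the boundary. Second, a caution the simulator makes visible: with very
few reference normals (three, as is common), the shared reference-mean
error acts as a common offset on every tumor's ratio, so the expression
tail alone is anti-conservative; the copy-number gate is what keeps the
concordance call specific, and concordance should not be read as an
expression-only differential test.

## shRNA vulnerability and lineage-specific essentiality

In the pooled screen, lower depletion scores mean stronger growth
inhibition (a flag flips the convention if needed). Per cell line,
shRNAs are ranked ascending and a gene's essentiality is the one-sided
KS-style top-enrichment of its hairpins — the unweighted running-sum
enrichment score of gene-set analysis, floored at zero. Its permutation
p-value against uniformly drawn same-size rank sets becomes the
vulnerability score $v = -\log_{10} p$, kept finite by the add-one
pseudocount and hence bounded by $\log_{10}(B+1)$ (B defaults to 1000; a
gene at the very bottom scores exactly 0, accepting the boundary of the
nominal open range). Because the null depends only on the universe size
and the hit-set size, one B-draw null per distinct shRNA-set size is
shared across all genes and cell lines — the identical null, drawn once,
which keeps the gene × line table tractable.

Lineage specificity is a per-gene Welch t-test of vulnerability scores
in the target lineage versus all other lines (the unequal-variance form,
since a 9-versus-91 split with a bounded, zero-inflated score cannot be
assumed homoscedastic), BH-corrected across genes at **q ≤ 0.1**, with
the extra requirement that the target-lineage mean exceed the rest —
essentiality must point into the lineage, so pan-essential genes are
excluded by construction.

## Survival screening

Overall survival is analysed on the five-year horizon: administrative
censoring at **60 months** is applied before any fit. Expression is
dichotomized at a configurable quantile, default **0.75** (high = top
quarter); the Kaplan–Meier estimator and log-rank test summarise group
differences, and Cox proportional-hazards models (Efron ties, suited to
month-resolution data) drive the screen: one univariate model per peak
gene and per clinical covariate, then every variable with univariate
Wald p < 0.05 enters a single multivariate model. Degenerate inputs are
handled deliberately: constant covariates are rejected up front,
collinear or completely separated fits come back flagged rather than as
errors, and non-convergence is an error.

## Evidence intersection

Layers are joined by gene symbol (case-sensitive; duplicated symbols in
the annotation are an error). Each gene gets five flags — in peak,
concordant, prognostic (univariate), prognostic (multivariate),
vulnerable — and genes are ranked by evidence count, then best peak q,
then vulnerability q, then symbol. The full table is emitted, not just
the winners, so downstream filtering choices stay with the analyst.

# The simulator: what it emulates, and what it does not

The generator plants known truth into data with the shape of a real
integrative study:

* **Copy number.** Events are additive on the log2 scale on a 5 × 1000
  marker grid (10 kb spacing): three focal events of ~15–20 markers
  (amplitude 1.0 ± 0.1 log2, prevalence 0.8 — a strong, recurrent
  amplicon/deletion) and two arm-level events (amplitude 0.5, prevalence
  0.6), over Gaussian marker noise of 0.3 log2, typical post-segmentation
  aCGH residual scale. Carriage is an independent Bernoulli draw per
  sample; normals carry no events. Additivity makes zero-noise runs
  exactly checkable, and opposite-direction events on shared markers are
  rejected as contradictory truth.
* **Expression.** 1000 genes tile the grid (5 markers each, so the
  gene↔marker map is closed-form); a gene's copy number is its marker
  mean. Dosage genes respond with slope β = 1 expression-log2 per
  CN-log2; everything else is baseline (per-gene level ~ N(8, 1)) plus
  N(0, 0.5) noise, against three reference normals — mirroring the
  common tumor-rich/normal-poor design.
* **Screen.** 100 cell lines, 9 of them the target lineage, 5 hairpins
  per gene; essential genes depress their hairpins' scores by 2.0 over
  unit noise, lineage-specific ones only in target-lineage lines.
* **Survival.** Exponential times at baseline hazard 0.04/month (median
  ~17 months, an aggressive-carcinoma scale) multiplied by
  exp(log-HR × high-expression) for planted prognostic genes, using the
  same dichotomization operation as the survival screen (one source of
  truth). The planted driver's log-HR is 1.2 (HR ≈ 3.3, on the scale of
  nodal-metastasis effects in this disease); chosen a priori so that a
  60-patient cohort with ~75% event fraction gives the univariate screen
  ~95% power — a cohort that could not see its own planted driver would
  test nothing. Censoring is uniform over 120 months (light random
  loss), then administrative at 60.

One gene ("G0541") carries all five marks and is the planted
full-evidence driver. Fixed seeds give byte-identical outputs, and the
cohort and screen use decoupled RNG streams.

What the simulator does **not** emulate: GC waves and probe-specific
effects, germline CNPs, subclonality and tumor purity, quantile
normalization artefacts, shRNA off-target/seed effects, or correlated
hazards beyond the planted genes. Passing the planted-truth suite
therefore shows the pipeline's statistics are correct and calibrated
under the stated generative model — not that the thresholds are optimal
for any particular real platform.

# Tests and problem sizes

The suite checks every primitive against an independent oracle (full
$2^n$ sign enumeration for the signed-rank null, running-sum evaluation
for the enrichment statistic, the literal step-up definition for BH,
direct summation for G, hand product-limit for Kaplan–Meier), calibrates
the type-I error of the signed-rank, Welch and log-rank tests at 2000
null replicates each, verifies permutation-p uniformity and null FDR
behaviour of the vulnerability screen, and measures planted-truth
recovery over 20 simulated cohorts at the default conditions plus Cox
hazard-ratio recovery over 50 cohorts of n = 500. These sizes keep the
whole suite in the ten-minute range on one core while leaving the
stochastic acceptance margins comfortably wide; they are stated here as
the package's chosen experiment sizes so that reruns are comparable.

One published worked example is bundled: a ten-region recurrent-peak
table from an esophageal squamous cell carcinoma cohort (121 genes in
peaks in total), used to exercise the candidate-collection stage on real
published values; unnamed peak members appear as placeholder symbols.
The corresponding patient-level validation-cohort records were published
only as a word-processor supplement and are not redistributable here, so
the bundled survival checks run on simulated cohorts with known hazard
ratios instead.

# Known limitations

* Peaks are contiguous significant runs: no peel-off, no wide-peak
  confidence intervals, no arbitration between co-amplified neighbours.
* The permutation null for recurrence treats markers within a sample as
  exchangeable; long-range waves would inflate significance and should
  be removed upstream.
* The concordance construction (two one-sample signed-rank tests plus a
  direction gate) applies the 1e-6 threshold per gene without
  multiplicity adjustment, matching its published use; interpret the
  flag as a screen, not an inference.
* The vulnerability permutation draws rank sets (gene-label null), not
  phenotype permutations; B = 1000 bounds achievable scores at ~3.
* Survival tooling covers right-censored, time-fixed covariates only —
  no time-dependent effects, no proportionality diagnostics.
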