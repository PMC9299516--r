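---
title: "nociceptR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nociceptR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

nociceptR quantifies stimulus-evoked Ca²⁺ signals in nociceptor-enriched
sensory neuron cultures at single-cell resolution and reduces them to one
population endpoint: the fraction of reactive cells. The pipeline has five
analysis stages — trace extraction, ΔF computation, reactivity calling,
concentration–response fitting, and transcriptome activation scoring — plus
a synthetic-data generator that provides ground truth for every stage.

The statistical model behind the endpoint is deliberately simple. Each
cell's recording is treated as

> baseline · exp(−bleach · t) + amplitude · template(t − t_stim) + noise,

and the evoked change ΔF = (response-window peak) − (baseline-window mean)
is compared against a well-specific noise threshold
T = min(mean + 3·SD, cap) estimated from negative-control (buffer)
stimulations. The 3-SD rule gives a nominal one-sided false-positive rate
of ≈ 0.13% per cell under Gaussian noise; the cap (default 18 intensity
units) guards against wells whose control stimulation itself evoked
responses (e.g. mechanically sensitised cultures), where mean + 3·SD would
runaway and mask real reactivity. A cell is reactive iff ΔF > T, strictly;
ties are non-reactive. The test suite verifies the false-positive budget
empirically (mean reactive fraction ≤ 0.005 over 10 pure-noise wells with
the cap disabled).

### ΔF conventions

* ΔF is peak-minus-baseline in **raw intensity units**, not ΔF/F. An
  absolute cap on the threshold is only meaningful in un-normalised units,
  and the fixed-gain imaging this assay uses makes raw units comparable
  within a plate. A mean-over-window response statistic and a median
  baseline are available as options (the median variant is robust to
  single-frame pipetting artifacts in the baseline).
* Time windows are half-open `[start, end)`; a frame belongs to a window
  iff its timestamp falls inside. Pixel coordinates are 1-based, following
  R's array convention.
* For the second and later stimuli of a double-stimulation protocol, the
  baseline is re-anchored to the 5 s (configurable) immediately preceding
  that addition. Without re-anchoring, a sustained first response (TRPV1
  plateaus retain ~90% of their peak) would inflate the second stimulus's
  ΔF by tens of units. With re-anchoring, the residual carry-over is the
  difference between the decaying first response during the re-baseline
  window and during the second response window, bounded in the simulations
  by ~2% of the first amplitude.

### Reactivity statistics

Technical replicates (wells) are averaged within a biological replicate
(independent differentiation) before cross-replicate statistics; SEM over
biological replicates is reported, and is `NA` — never 0 — for a single
replicate. Two-condition designs use a two-sample t-test (paired option);
multi-condition designs use one-way ANOVA with Dunnett comparisons against
the reference condition, since the assay's designs compare treatments
against a control; all-pairs Tukey is available. The type-I error of the
two-condition path is checked by simulation (1000 null repetitions,
rejection rate within 0.05 ± 0.02).

The control-ΔF source for the threshold is ambiguous in principle: it can
come from a buffer stimulus within the same well, or from dedicated control
wells. The default resolves per well: use the same-well buffer stimulus
when the protocol contains one, otherwise pool the control wells of the
same plate; the mode used is recorded per well in the outputs.

### Concentration–response

The fitted response is the reactive fraction (not amplitude), matching how
the endpoint is used. The model is a four-parameter logistic on log10
concentration; agonist curves have positive Hill slope and report EC50,
antagonist curves negative slope and IC50. Zero-concentration controls are
kept aside from the logistic (log10 undefined) and can anchor the bottom in
fixed-bottom mode (3 points suffice there; 4 otherwise). Fitting uses
Levenberg–Marquardt least squares, unweighted by default with optional
1/SEM² weights. Non-convergence, a flat response, or a midpoint more than a
decade outside the tested range yields a flagged result, never an
exception. Noise-free logistic data are recovered within 1% relative error;
a stochastic antagonist series (binomial per-cell blocking, planted IC50
3 × 10⁻⁷ M, 500 cells × 3 replicates) within a factor of 2.

### Transcriptome activation scores

The transcriptome module follows the conventional chain CPM → per-time-point
fold changes vs baseline → DEG filter → over-representation → activation
scores. Differential expression is intentionally a lightweight stand-in:
per-gene pooled two-sample t-tests on log2(CPM + 1), BH-adjusted across
genes within each time point, filtered at adjusted p < 0.05 and fold change
≥ 2 (|log2FC| ≥ 1, boundary inclusive). Negative-binomial shrinkage
machinery is out of scope; precomputed p-values can be supplied to use any
external test. The fold-change baseline defaults to the earliest time point.

Gene-set over-representation is the one-sided hypergeometric tail on the
measured universe, BH-adjusted across sets; sets with adjusted p < 0.05 are
"oGOs", optionally post-filtered to the top n (default 50) by p-value. The
activation score of a set at a time point is

> (% of measured members that are DEGs) × (mean |log2FC| of those DEGs),

zero when no member is a DEG. Two readings of "average fold change" are
defensible — linear fold change or log2, signed or absolute. The default is
the mean of |log2FC| over the significant members: it treats up- and
down-regulation symmetrically and is stable under scale changes; linear and
signed variants are config options. The percentage denominator is the set
members actually measured on the panel, not the full annotation, because
targeted sequencing panels do not cover every annotated gene. Group
trajectories average scores over the member sets of a superordinate group,
with SEM across sets and a paired t-test (pairing by set id) of each time
point against a reference time point.

## The synthetic-data generator

The generator defines the study conditions the pipeline is tested under:

* **Recording geometry**: 45-s recordings with stimuli applied after a 10-s
  baseline, at 2 frames/s (90 frames). The acquisition rate of the original
  assay is not a published constant; 2 fps is a config default typical of
  plate-level Ca²⁺ imaging and appears in no algorithm.
* **Kinetic templates**: piecewise linear rise to a unit peak, then
  exponential decay towards a plateau fraction. The two archetypes are a
  fast-inactivating purinergic (P2X3-like) transient (plateau ≈ 0.05, decay
  3 s) and a sustained TRPV1-like response (plateau 0.9, decay 10 s). The
  template family is a minimal parametric stand-in for observed trace
  shapes; it is sufficient to test classification and window logic, and all
  parameters are config-exposed.
* **Population mixture**: responder classes none / A-only / B-only / both
  default to 0.25 / 0.40 / 0.10 / 0.25, the observed split of purinergic-
  and capsaicin-responsive subpopulations in nociceptor-enriched cultures.
* **Amplitudes and noise**: responder amplitudes N(60, 15²) truncated at 0
  (well above the cap of 18), per-frame Gaussian noise SD 2, baseline
  fluorescence N(100, 10²), photobleaching 0.001/s applied to the baseline
  only (a mild negative drift, ~4% over 45 s, without coupling to response
  amplitude).
* **Negative-control additions**: any stimulus not labelled A/B evokes an
  "artifact" amplitude in *every* cell, default 0. Elevating it models
  mechanically sensitised (allodynia-like) cultures; the acceptance test
  reproduces the qualitative drug pre-treatment result — buffer-evoked
  fractions significantly elevated only in the sustained pre-treatment
  scenarios — with artifact amplitudes of 40 vs 4 units.
* **Rendering**: wells can be rasterised to 16-bit multi-frame TIFFs as
  isotropic Gaussian spots (integrated intensity ∝ trace value) on a
  constant background, cells on a jittered grid with enforced minimum
  spacing. Detection on rendered stacks recovers positions within 2 px and
  extracted traces correlate ≥ 0.99 with the planted ones in the noise-free
  case.
* **Counts**: negative-binomial with a shared dispersion (default 0.05) and
  log-normal gene abundances; a configurable fraction of genes carries a
  planted log2FC (uniform magnitude in [1, 3], random sign) versus the
  first time point, either as a step or as a linear ramp across time points
  (the ramp emulates progressive maturation and drives the PCA gradient
  check). Per-gene dispersions and library-composition effects beyond
  renormalisation are not modelled.

What passing tests on these data do **not** show: robustness to motion,
focus drift, overlapping somata, indicator saturation, non-Gaussian photon
noise, or cross-desensitisation between receptors — none of which the
generator emulates. Results on real recordings depend on segmentation
quality upstream of the statistics.

## Numerical and degenerate-input choices

* Thresholds require ≥ 2 control values (sample SD undefined below that);
  SD uses the n − 1 denominator, the conventional estimator for the small
  control samples involved.
* `classify` uses strict `>`; a ΔF exactly at the threshold is
  non-reactive.
* t-tests on exactly identical samples (zero variance, zero difference)
  return p = 1 rather than an error; zero variance with a non-zero
  difference returns p = 0.
* Cell detection: temporal maximum projection, Gaussian smoothing
  (σ = 1.5 px), median background subtraction, strict 8-neighbour local
  maxima above 3 × MAD prominence, greedy acceptance (brightest first)
  under a minimum-separation constraint (6 px). A uniform stack yields zero
  ROIs; two cells closer than the separation merge into one ROI by
  construction.
* Hill fits start from data-derived values (top/bottom from the response
  range, midpoint from the half-maximum crossing) and flag rather than
  throw on failure.
* BH adjustment and ANOVA/t-test/PCA primitives delegate to base R
  (`p.adjust`, `aov`, `t.test`, `prcomp`); Dunnett comparisons to
  multcomp; the test suite cross-checks BH and the hypergeometric tail
  against exhaustive enumeration oracles on small instances.

## Problem sizes

The shipped tests run at desk scale, chosen to keep the full suite under a
minute while leaving the statistical assertions well-powered: wells of
25–2000 cells, 100-seed recovery loops at n = 1000 cells (3-binomial-SE
criterion), overlap recovery at n = 2000, 1000-repetition type-I
simulation, count matrices of 200–2000 genes with 2–7 time points and 2–50
replicates. The generator scales to larger settings without code changes.

## Known limitations

* The ΔF operator assumes a stable baseline within each window; slow
  oscillations or strong photobleaching curvature bias it (the bleach bias
  is bounded by baseline × bleach rate × window length and is negligible at
  the default rate).
* The DEG stand-in has no variance moderation; at 2–3 replicates its power
  is below that of shrinkage-based methods, which matters if it is used
  for discovery rather than for driving the activation-score plumbing.
* The segmentation is a fixed-radius spot detector; it is not intended for
  confluent cultures or neurite-level analysis.
* AVI ingestion is not implemented; TIFF is the canonical stack container,
  and pre-extracted trace CSVs bypass imaging entirely.
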