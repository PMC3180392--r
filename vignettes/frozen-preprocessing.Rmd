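---
title: "Frozen-parameter preprocessing: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frozen-parameter preprocessing: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frmakit)
```

This vignette is the package's own account of the science it implements:
the probe-level model, the estimators behind each frozen parameter
vector, the tunable constants and why they default as they do, what the
simulators do and do not emulate, and the design decisions taken where
more than one reasonable choice existed.

## The probe-level model

Expression microarrays measure each transcript with a *probeset* of
several probes. On the log2 scale, the intensity of probe $j$ of a
probeset on array $i$ belonging to batch $k$ is modelled as

$$Y_{ji} = \theta_i + \phi_j + \gamma_{jk} + \varepsilon_{ji},
\qquad \gamma_{jk} \sim N(0, \tau_j^2),
\qquad \varepsilon_{ji} \sim N(0, \sigma_j^2).$$

* $\theta_i$ — the quantity of interest: the probeset's expression on
  array $i$.
* $\phi_j$ — the probe effect: a systematic, sequence-driven offset of
  probe $j$, constrained to sum to zero within the probeset so that
  $\theta$ carries the probeset's location. Probe effects are large in
  practice (spanning orders of magnitude in raw intensity) but highly
  reproducible, which is why they can be frozen.
* $\gamma_{jk}$ — a batch-specific probe shift: probe $j$ behaving
  differently in lab/tissue/scan-date group $k$. Its variance $\tau_j^2$
  is the key quantity the freeze/thaw approach adds over RMA: probes
  with large $\tau_j^2$ are systematically unreliable across batches
  and are down-weighted when any new array is summarized.
* $\varepsilon_{ji}$ — per-observation noise with probe-specific
  variance $\sigma_j^2$.

A *batch* is whatever grouping the user supplies — tissue-by-experiment
combinations for platform-wide training, scan dates within a single
study, or anything else; the package only requires the labels.

## The five (plus one) frozen vectors

`make_vectors()` produces, in this order:

1. **Reference distribution** — the mean order-statistic distribution of
   the background-corrected, log2-transformed training arrays. New
   arrays are quantile-normalized *to* this fixed vector, which is what
   severs the dependence between arrays.
2. **Probe effects** $\hat\phi_j$ — from a per-probeset robust two-way
   fit (below).
3. **Within-batch variance** $\hat\sigma_j^2$ — the mean over batches of
   the within-batch sample variance of probe $j$'s residuals.
4. **Between-batch variance** $\hat\tau_j^2$ — the method-of-moments
   estimate $\max\!\big(v_f,\; \mathrm{Var}_k(\bar r_{jk}) -
   \hat\sigma_j^2 / \tilde k\big)$, where $\bar r_{jk}$ are the
   batch-mean residuals, $\tilde k$ is the harmonic-mean batch size
   (reducing to the textbook balanced-design estimator when batch sizes
   are equal), and $v_f$ is the variance floor.
5. **Probeset average SD** — the mean over the probeset's probes of
   $\sqrt{\hat\sigma_j^2 + \hat\tau_j^2}$. The vector is computed and
   stored for completeness; the single-array summarization below does
   not consume it (it belongs to multi-array random-effect
   summarization variants, which are out of scope here).
6. **Median SE** (optional) — the per-probeset median of the standard
   errors obtained by applying the frozen model back to each training
   array. This is the denominator of the quality score: it defines what
   a "typical" standard error looks like for each probeset, so the
   score for a new array is its SE relative to that norm. Computing it
   by self-application costs one extra pass over the training arrays
   and requires no additional data.

The bundle is stored as a directory of TSV files (one per vector, ids
alongside values, full double precision) plus a JSON metadata file.
Plain text keeps bundles diffable and shareable and makes a mismatched
annotation detectable when a bundle is reloaded. The median-SE vector is
stored per probeset: it normalizes probeset-level standard errors, so a
probe-level layout would have no consumer.

## Estimators

### Background correction

Raw intensities are modelled as normal optical noise plus exponential
signal ("normexp"). The correction replaces each observed intensity by
the posterior mean of the signal — a truncated-normal expectation,
computed on the log scale so the Mills ratio stays finite deep in the
lower tail; it is strictly positive and monotone.

Parameter estimation starts from the classic kernel-density heuristic
(noise mean at the density mode of the intensities, noise SD from the
spread below the mode, signal rate from the mean excess above it), then
refines by maximizing the closed-form convolution likelihood inside a
box around those starting values. The refinement matters: when
essentially all probes carry signal, the raw density mode sits well
above the true noise mean (by roughly $\sigma\,\Phi^{-1}$-sized terms)
and simulation shows it misses the truth by 20–35%, while the bounded
maximum-likelihood fit recovers all three parameters within a few
percent. The box (mean within $-6\sigma_0/{+}2\sigma_0$ of the mode,
scale within $e^{-3}$–$e^{1}$, rate within $e^{\pm 2}$ of their
heuristic starts) exists because the likelihood is unbounded along a
large-$\sigma$/large-rate ridge when the data depart from the
normal+exponential form, as real probe intensities always somewhat do;
the box keeps the fit in the physically meaningful basin. With
`method = "mode"` the unrefined heuristic is available.

Background parameters are identifiable only when some probes are
background-dominated. Real arrays always have such probes (unexpressed
transcripts); the training-set simulator deliberately does not (see
below), which is why the recovery experiments run with
`bg_correct = FALSE`.

### Quantile normalization

All normalization happens on the log2 scale, against a nondecreasing
reference vector; the value at the probe holding rank $r$ becomes
element $r$ of the reference. Tied input values receive the mean of the
reference values at the ranks they span — the deterministic,
input-order-independent tie policy. Joint (RMA-style) normalization is
the same operation against the mean order-statistic reference of the
arrays at hand. Working on the log2 scale means the frozen reference is
stored in the units every later step uses; it differs from raw-scale
normalization only in taking the arithmetic mean of log2 order
statistics rather than the log of the arithmetic mean, a convention
with no consumer-visible consequence.

### Robust probe-effect fit

`fit_probe_effects()` fits $Y_{ji} \approx \theta_i + \phi_j$ by
iteratively reweighted least squares with Huber weights
($c = 1.345$, 95% efficiency at the normal), residual scale
re-estimated each iteration by the MAD about zero, at most 50
iterations, convergence at $10^{-6}$ maximum parameter change.
Identifiability: $\sum_j \phi_j = 0$ within each probeset; $\theta$
absorbs the probeset mean. A single-probe probeset degenerates to
$\phi = 0$, $\theta_i = Y_{1i}$. When residuals vanish (noise-free
input) the scale estimate hits its floor and all weights are 1, giving
the exact least-squares solution.

### Summarization of a new array

With $y_j$ the normalized log2 intensity and $v_j = \hat\sigma_j^2 +
\hat\tau_j^2$ (floored at the variance floor), the expression estimate
solves a weighted robust location problem for $y_j - \hat\phi_j$: base
weights $1/v_j$, multiplied by Huber weights on
$(y_j - \hat\phi_j - \hat\theta)/\sqrt{v_j}$, iterated to $10^{-8}$.
This realizes both kinds of down-weighting — persistent (frozen
variances) and incidental (this array's outliers). The SE is
$\sqrt{1/\sum_j w_j}$, the natural precision-weighted form; the quality
score divides it by the frozen median SE, so the SE convention cancels
in the ratio.

### Location conventions

Median polish (the RMA summarizer) leaves its row effects centered at
zero *median*, while the frozen probe effects sum to zero. A polish
decomposition is unique only up to constant shifts between components,
so `median_polish()` re-centers both effect vectors to zero mean and
absorbs the compensating constants into the overall term. With both
summarizers on the same sum-to-zero convention, frozen-pipeline and
median-polish expression values are directly comparable; without this,
every probeset would carry a spurious offset equal to
median-minus-mean of its probe effects (≈0.15 log2 for typical
probe-effect spreads), which is a bookkeeping artifact, not a real
disagreement.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `huber_c` | 1.345 | SDs | Robustness/efficiency trade-off of all Huber fits |
| `max_iter` | 50 | — | IRLS iteration cap (training and summarization) |
| `convergence_tol` | 1e-8 | log2 | Summarization convergence on $\hat\theta$ |
| `variance_floor` | 1e-8 | log2² | Lower bound on variance estimates; keeps weights finite and the moment estimator nonnegative |
| `alpha` | 0.05 | — | Significance level of the batch-effect diagnostics |
| `bg_correct` | TRUE | — | Apply normexp correction (disable for data already on a corrected scale) |
| `compute_median_se` | TRUE | — | Train the optional sixth vector |

The batch-effect F statistic compares the between-batch to the
within-batch mean square of each probe's residuals with
$(B-1, N-B)$ degrees of freedom. The summary "fraction significant"
uses unadjusted $p < \alpha$ — the convention for describing the
*extent* of batch structure — and a Benjamini–Hochberg-adjusted
companion is always reported alongside for readers who want a
multiplicity-controlled number.

## The simulators

`simulate_training_set()` realizes the additive model exactly: per
probeset a baseline abundance (uniform on log2 7–12), per array an
effect $\theta_i$ that is the sum of an individual term (SD 0.1) and a
batch-level brightness shift shared by the batch (SD 0.3, the
scanner/lab effect that makes different trainings produce different
reference distributions), probe effects $N(0,1)$ centered within
probeset, batch shifts and noise per the model. Probe noise SDs follow
a scaled-chi distribution with mean 0.25; a quarter of probes carry
batch-shift SDs (scaled chi, mean 0.5), the rest none — the regime in
which roughly a fifth of probes show detectable batch effects, matching
what large heterogeneous compendia display. Intensities are
exponentiated to the raw scale with *no* optical background, so
recovery experiments isolate the training estimators.

`simulate_spikein()` builds the benchmark layout: a cyclic latin square
of doubling concentrations (including 0 pM) over `n_groups` probeset
groups, replicated as `n_batches` blocks that double as batches, plus
null probesets constant across arrays. Spiked signal is
$\log_2(c + c_0)$ above a base, so the ideal signal-detection slope is
1 well above the soft floor $c_0 = 0.25$ pM and compresses below it —
as real hybridization does. Here optical background *is* added
(normal, mean 30, SD 6) and null baselines span log2 3–12 so that a
realistic fraction of probes is background-dominated, making the
background parameters identifiable and exercising the full pipeline.

What the simulators do **not** emulate: probe-sequence-driven effects
(GC content), intensity-dependent variance beyond the floor
compression, cross-hybridization, spatial artifacts, or heavy-tailed
outlier contamination. Passing tests therefore demonstrate correctness
of the estimators under the stated model and the qualitative behaviour
of the pipeline — not performance claims about any particular real
platform.

## Evaluation protocols and their designs

* **Consistency (MAD) experiment** — for each training design, repeated
  balanced samples are drawn from a 2,000-array pool (40 batches × 50
  arrays; 100 probesets × 4 probes), vectors trained, and one held-out
  array preprocessed; the per-probeset MAD (scaled by 1.4826, the
  normal-consistency constant — the comparisons are scale-invariant, so
  the constant is cosmetic) across 20 replicates is summarized by its
  median and IQR. Twenty batches of five give visibly smaller MADs than
  five batches of five: consistency is driven by how many batches the
  training sees.
* **Spike-in benchmark** — 14 concentration groups × 9 blocks (126
  arrays), 42 spiked + 400 null probesets of 8 probes. Accuracy is the
  slope of expression on log2 concentration, per stratum; strata are
  tertiles of the distinct positive concentrations (for spiked
  probesets) and tertiles of mean observed expression (for nulls); the
  boundaries are a design choice exposed as `n_strata`. Precision is
  the SD and the 99.5th percentile (inverted-ECDF quantile, so exactly
  0.5% of null ratios exceed it) of null log-ratios over adjacent
  within-block array pairs — within-block pairing is the conservative
  choice: it cancels batch shifts, so the frozen pipeline's precision
  advantage seen here comes from variance-based down-weighting alone.
  SNR is slope over null SD; POT ranks every probeset by observed
  absolute fold change in each pair with a true 4-fold change and
  counts qualifying probesets in the top list.
* **Reference-sharing experiment** — two trainings on disjoint batch
  subsets preprocess a common test set; with per-training references
  the expression difference distribution is offset by the difference in
  reference levels (driven by batch brightness), and sharing a single
  reference removes that offset. This isolates normalization as the
  source of between-training bias, with probe-effect estimation
  responsible for the residual spread.

Problem sizes throughout were chosen as the smallest designs at which
the estimators' sampling noise is clearly below the effects being
demonstrated; the full suite runs in well under two minutes of compute
per experiment.

## Degenerate inputs and numerical corners

* Constant intensity vectors: background estimation refuses (degenerate
  density).
* Posterior-mean correction far below the noise mean: the closed form
  suffers cancellation; the implementation switches to the asymptotic
  $\sigma^2/|b|$ limit, preserving positivity and monotonicity.
* Batches with fewer than two arrays are excluded from variance
  estimation and diagnostics; fewer than two usable batches is an
  error.
* Negative moment estimates of $\tau^2$ truncate to the variance floor.
* A probeset whose fit fails is dropped, recorded in bundle metadata,
  and training re-runs on the reduced probe set so the frozen reference
  always spans exactly the probes it will normalize.
* Ties in quantile normalization average the spanned reference values;
  sampling and ordering are radix-sorted so results do not depend on
  the locale.

## Known limitations

* Numeric identity with other implementations of the same lineage is
  not claimed: the robust estimator, variance decomposition and
  summarization variant are specified here, not reverse-engineered.
* The single-array mode does not implement multi-array random-effect
  summarization; the probeset-average-SD vector is produced for
  downstream consumers but unused internally.
* Background parameters cannot be estimated from arrays in which every
  probe carries signal; such data should be processed with
  `bg_correct = FALSE`.
* The consistency and benchmark experiments are simulation-scale
  analogues; absolute values of their metrics depend on generator
  settings and should be read comparatively, not as platform constants.
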