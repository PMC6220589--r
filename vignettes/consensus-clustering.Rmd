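---
title: "Consensus clustering of visuomotor response profiles: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of visuomotor response profiles: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fefclust)
```

This vignette is the package's account of its science: the models and
procedures it implements, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was open.

## The task and the data model

Units are recorded during a memory-guided saccade: after 500 ms of
fixation a peripheral target is flashed for one video refresh at 8°
eccentricity at one of eight locations 45° apart; a variable delay of
300–800 ms follows before the go signal, and the saccade is made from
memory. The task dissociates visual from motor activity in time, which
is what makes alignment-specific response shapes (visual transients,
delay activity, presaccadic ramps, perisaccadic suppression)
identifiable.

A unit is a set of trials, each with a stimulus-onset time, a saccade
time, a correctness flag, a target location and a spike train; waveform
samples are optional. Analysis uses only correct trials with the target
in the unit's receptive field and at least five spikes.

## Spike density functions

SDFs are computed by convolving each trial's spike train with a causal
kernel shaped like a postsynaptic potential,
$k(t) \propto (1 - e^{-t/\tau_g})\,e^{-t/\tau_d}$ for $t \ge 0$. The
package defaults to the standard postsynaptic-potential constants
$\tau_g = 1$ ms (growth) and $\tau_d = 20$ ms (decay), fully
configurable in `sdf_kernel()` since conventions vary across
laboratories. The kernel is normalized to unit area so
SDFs are in spikes/s — required for screening criteria expressed in
rate units to be meaningful. Convolution is computed by exact kernel
translation at 1 ms resolution (no FFT round-off), and per-trial SDFs
are averaged over eligible trials.

Two alignment windows are kept: stimulus-aligned −200..300 ms and
saccade-aligned −300..200 ms (501 samples each). A unit with no eligible
trial has no stable estimate and is dropped with an explicit signal. An
optional split-half reliability gate (Pearson *r* between SDFs of two
random trial halves) is available for stricter stability screening but
is **off by default**: there is no canonical operational definition of a
"stable" SDF estimate, and applying an invented exclusion silently would
change the sample.

## Screening

Four independent criteria: waveform SNR (peak-to-trough of the mean
waveform over the SD of concatenated residuals; threshold 2.5 by
default, system-dependent in practice), at most 10% of inter-spike
intervals below 2 ms, baseline rate of at least 5 spikes/s, and nonzero
SDF values in the visual (50–150 ms post-stimulus) or perisaccadic
(−50..50 ms) epochs. The baseline epoch is −200..−100 ms before
stimulus onset everywhere in the package — screening, scaling and the
traditional classifier share one definition. Whether the original
baseline-rate screen used this epoch or the whole recording is not
stated; the pre-stimulus epoch is the conservative, task-independent
choice. Units without waveforms skip the SNR criterion with a logged
notice rather than being excluded.

## The preprocessing grid

Each pipeline is a (scaling, measurement, metric) triple; the grid is
6 × 4 × 2 = 48.

**Scalings.** Three are fixed by the analysis design: no scaling,
z-scoring against the baseline epoch's mean and SD, and z-scoring
against the whole trial. The identities of the remaining three scalings
are not recoverable from the text, so the registry completes the six
with natural members of the same family: baseline subtraction, division
by the trial maximum (peak normalization), and min–max to [0, 1]. The
consensus stage is agnostic to this choice — its median is designed to
absorb non-optimal pipelines — and the set is configuration, not ground
truth. The quality of a scaling for cross-unit comparison is summarized
by `skewness_index()`: the mean over time points of the cross-unit
sample skewness (z-whole-trial is the best-behaved by this criterion on
synthetic data).

**Measurements.** Epoch means (6), epoch slopes (6), both (12), or the
full concatenated SDF (1002 samples). The six epochs are half-open
`[start, end)` intervals: baseline (−200, −100), early/late visual
(50, 100), (100, 150) post-stimulus, early/late presaccadic
(−100, −50), (−50, 0), and postsaccadic (50, 100). Half-open intervals
prevent a shared boundary sample (e.g. 100 ms) from being counted in
two epochs. "Slope" is the mean over the last 10 ms of the epoch minus
the mean over the first 10 ms — an endpoint-window difference, robust
to single-millisecond noise; the window width is configurable.

Every measured feature is z-scored across the sample (uniformly for all
four measurements, including per-time-point for the SDF measurement) so
that all epochs, means and slopes weigh equally. Constant features map
to zeros, keeping them inert under Euclidean distance instead of
propagating division by zero.

**Metrics.** Euclidean distance in feature space, or correlation
distance $1 - \rho$ (pattern similarity, discarding absolute rates). A
zero-variance feature vector has undefined correlation; such units are
assigned the maximal distance 2 to every other unit and flagged, which
records them as "maximally unlike any modulated unit" while preserving
auditability.

## Agglomeration, cuts, and the number of categories

Group-average linkage is implemented from its definition: the distance
between two groups is the arithmetic mean of all cross-group member
pair distances, i.e. a size-weighted mean that keeps uneven group sizes
from skewing similarity. Internally the package uses the exact
Lance–Williams update for this rule; tests verify every height against
an exhaustive double-loop oracle and against an independent
average-linkage library. Ties in the minimal pair are broken toward the
pair containing the smallest original unit indices, making every run
deterministic.

A categorization at *k* is the **most recent** merge state containing
exactly *k* groups of at least `min_members` (10 by default) units;
everything outside those groups is `uncategorized`. If no state
qualifies, the result is all-uncategorized with *k* = 0 — absence is a
valid answer, not an error.

For single pipelines the number of categories is chosen by a gap
procedure: observed intracluster dispersion (size-weighted mean
within-category pairwise distance, uncategorized units excluded) is
compared against 20 reference sets drawn uniformly within the
per-dimension range of the features. The strict rule takes the first
*k* whose gap reaches the next gap minus its null SD; all qualifying
*k* are also reported as lenient candidates for inspection, because the
lenient adjudication is a human judgement the batch pipeline should
expose rather than make. When no usable null exists (distance-only
input, or degenerate nulls) the fallback is the inflection of the
dispersion curve — the largest second difference, i.e. the point where
the reduction in dispersion slows most; if even that is undefined the
smallest evaluable *k* is returned on parsimony grounds. The number of
null sets and their construction are configuration with these defaults,
as no canonical values are available.

## Consensus

Each pipeline's distance matrix is z-scored internally over its
off-diagonal upper triangle — including the diagonal zeros would
distort the mean and SD — and the composite entry for each unit pair is
the median across pipelines, which prevents skewing by non-optimal
pipelines. The composite diagonal is set to the composite minimum so
that a unit remains nearest to itself even though composite entries are
signed z-scores. With an even number of pipelines the median is the
midpoint of the central pair. The composite is invariant to pipeline
order and to rescaling any input matrix by a positive constant.

Because no physiologically sensible null set exists for a composite of
z-scored matrices, the consensus stage replaces the gap procedure with
two membership criteria: each category needs ≥10 members, and at most
10% of units may remain uncategorized. The largest *k* satisfying both
is selected; if none does, the root categorization (*k* = 1) is
returned with an explicit flag.

## Quality statistics

**Penalized RoV.** For category *c* with members *i* and time points
*t* of the scaled SDF, the modulation strength is the temporal variance
of the category mean, $MS_c = \sum_t (\bar X_{c,t} - \bar X_{c,.})^2 / N_t$,
and the ratio of variances at *t* is the within-category variance over
$MS_c$. Ratios are averaged over time, then categories, then multiplied
by $\sqrt{N_c}$ as an oversplitting penalty. Smaller is better; the
index has no absolute benchmark and is used comparatively. A category
whose mean is constant in time has an undefined ratio and is excluded
from the grand mean with a warning. The time base is the same
1002-sample concatenation used by the SDF measurement, scaled with the
whole-trial z-score (the best-behaved scaling by the skewness
criterion) when the scheme under evaluation does not come with its own
scaling.

**ARI and signed χ².** The adjusted Rand index is computed from the
contingency table's pair counts; `uncategorized` counts as an ordinary
category, since the comparison of interest includes the unclassified
column. Significance is by independently permuting each labelling;
`p` is the proportion of shuffled ARI values strictly exceeding the
observed one (no +1 correction — the definition is the plain
proportion). The signed χ² is $(O - E)/E$ per cell with *E* from the
marginals — each observed co-assignment count normalized by the count
expected under independence. Cells with *E* = 0 are masked. A bootstrap z-score
per cell comes from the same shuffling scheme.

**Feature tests.** Kruskal–Wallis omnibus tests per biophysical factor
across categories (uncategorized units are excluded, since they form no
coherent group whose features could differ), with follow-up tests within declared super-groups (visual /
visuomovement / movement families).

## Cross-validation

"SVD classifier with a linear kernel, no explicit regularization" is
operationalized as multiclass linear least squares: one-hot labels are
regressed on principal-component scores via the pseudoinverse (computed
by singular value decomposition), and the prediction is the argmax of
the fitted scores, ties to the lowest category index. Principal
components are computed **once** from the labelled units' rows of the
composite matrix (column-centred) and held fixed across folds — the
components describe the composite geometry, which does not depend on the
labels being validated; recomputation inside each fold is available behind the
`pca_per_fold` flag. Leave-one-out predictions are obtained with the
closed-form hat-matrix identity
$\hat y_{-i} = (\hat y_i - h_{ii} y_i)/(1 - h_{ii})$, which is
algebraically identical to refitting per fold (verified against an
explicit refit oracle in the tests) and makes the 1000-shuffle control
cheap.

One property of this control deserves note: under label permutation the
held-out unit's own class is depleted by one in the training marginals,
so the mean shuffled accuracy sits slightly **below** the nominal
$1/k$ (and below $\sum_i p_i^2$ for unbalanced labels) — about one
percentage point at a few hundred units. This is a property of
leave-one-out itself, not an implementation artifact, and the package's
chance-control checks therefore use the spread of the shuffle
distribution, not the standard error of its mean, as the comparison
scale.

## The synthetic generator

The generator exists so that every downstream stage is testable with
known ground truth. It emulates: the task timeline (fixation 500 ms,
target flash, 300–800 ms uniform delay; the go-to-saccade reaction time
defaults to uniform 150–250 ms, a typical memory-guided latency range); eight locations with Gaussian
receptive-field attenuation (width 60°) around each unit's single
preferred location (only preferred-location trials feed the SDF); the
strongly right-skewed per-unit trial counts (log-normal pinned at
median 34, truncated to [4, 317]); and ten rate archetypes — two
visual-only cells with peak latencies 74 and 136 ms (the later one with
delay activity), visuomovement cells crossing early (70 ms) and late
(161 ms) visual peaks with clipped versus slowly decaying saccadic
discharge and with or without delay activity, a postsaccadic-transient
cell, a near-pure movement cell with modest visual response, a
visual-"off" cell with a clipped presaccadic ramp, and a fixation-like
cell suppressed around the saccade. Beyond the anchored latencies, the
template rates are free parameters with realistic FEF magnitudes (baselines ~10–30 spikes/s, transients
60–80 spikes/s); they are documented as such and fixed.

Spikes are drawn from an inhomogeneous Poisson process by thinning —
the simplest process whose Fano factor of ~1 matches the variability
metrics' reference point. Visual and delay terms are anchored to the
stimulus, motor and suppression terms to the saccade, summed and
rectified at zero. Within-template variability applies log-normal gain
(SD 0.15) to the modulation terms, log-normal scaling (SD 0.15) to the
baseline, and Gaussian jitter (SD 5 ms) to the visual latency.
Suppression depth scales with the unit's baseline rather than the
excitatory gain, since a cell cannot be suppressed below zero rate.
Waveforms are biphasic with deflections of 100 and 50 µV separated by
the template's spike width, plus white noise (SD 10 µV), giving an SNR
near 15. Default population: 20 units per template (twice the
minimum-membership criterion, so recovery tests are not
membership-limited), 5% error trials.

What it does **not** emulate: eye-movement traces, LFPs, error-trial
dynamics (incorrect trials are only flagged), non-Poisson spiking
(bursting, refractoriness beyond thinning), electrode drift, or sorting
contamination. Passing recovery tests on this generator therefore shows
that the pipeline's inference machinery is correct under its own
assumptions — not that real FEF data contain ten categories.

## Numerical choices and degenerate inputs

- All epochs and windows are half-open `[start, end)` in ms; stimulus
  onset and saccade initiation each define t = 0 for their alignment.
- Zero baseline SD under baseline z-scoring, an all-constant SDF under
  whole-trial z-scoring or min–max, and a non-positive peak under peak
  normalization all flag the unit and zero its series rather than
  dividing by zero.
- Merge ties and classifier argmax ties break toward the smallest
  index; all stochastic steps take explicit seeds and restore the
  caller's RNG state.
- Gap dispersions of zero or missing cuts drop individual *k* values
  from the comparison instead of voiding the whole curve.

## Problem sizes

The test suite exercises the full default population (10 templates ×
20 units, skewed trial counts, ~15 s per seed for the complete
pipeline) across five seeds, plus oracle checks on hundreds of small
random instances (8–12 units) where exhaustive enumeration is exact.
The acceptance script repeats the complete consensus analysis on five
independent 200-unit populations. These sizes give stable recovery
statistics while keeping a full run in minutes on one core.

## Known limitations

- The three unnamed scalings are a declared configuration; a different
  completion of the six would change individual pipelines (by design,
  the consensus median is the mitigation).
- The gap procedure's uniform reference is known to favour splitting
  Gaussian data; the consensus stage avoids it entirely via the
  membership criteria.
- RoV is undefined for time-constant category means and is reported
  comparatively, never absolutely.
- With strongly unbalanced categories the LOO chance control should be
  compared against $\sum_i p_i^2$, not $1/k$.
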