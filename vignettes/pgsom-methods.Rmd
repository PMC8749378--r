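---
title: "Growing and pruning self-organizing maps for activity recognition: models and methods"
author: "pgsom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing and pruning self-organizing maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wearable-sensor activity recognition usually has abundant raw data but few
labels. The approach implemented here trains a vector quantizer — a
self-organizing map whose lattice grows and shrinks to fit the data — with
no labels at all, and only afterwards spends a small labeled subset to name
the neurons. Classification of a new sample is then a nearest-neuron lookup.

Three network modes share one training loop:

* **SOM** — a fixed `som_rows` x `som_cols` lattice; only weights adapt.
* **GSOM** — starts from a 2 x 2 square and adds neurons at the lattice
  boundary wherever quantization error accumulates.
* **PGSOM** — GSOM plus pruning: neurons that have not won for more than `M`
  consecutive presentations are deleted.

## One presentation

For an input $x$ presented to the map with neuron weights $w_i$:

1. **Winner**: $d_i = \lVert x - w_i \rVert^2$; the winner minimizes $d_i$,
   ties broken by lowest neuron id.
2. **Error accumulation**: the winner's cumulative quantization error (CEQ)
   gains $\eta\, d_{winner}$.
3. **Learning-rate decay**: $\eta \leftarrow \max\{\eta_{\min},
   (1 - R/|\Phi|)\,\eta\}$ where $|\Phi|$ is the current neuron count. See
   *Decay cadence* below.
4. **Weight update**: the winner moves plainly toward the input,
   $w \leftarrow w + \eta (x - w)$; each occupied 4-neighbor moves toward
   the winner's pre-update weight, damped by its own distance to the input:
   $w_i \leftarrow w_i + \eta\,(w_{winner}^{old} - w_i)\, e^{-d_i/\tau}$.
5. **Growth** (GSOM/PGSOM): if the winner's CEQ reaches the growth threshold
   $GT = -D \ln(SF)$ and the winner has free neighbor slots, one neuron is
   created in every free slot and the winner's CEQ resets to zero. An
   enclosed (interior) winner instead keeps half its CEQ and spreads the
   other half equally over its four neighbors — the total is conserved.
6. **Ages**: winner and newborns get age 0, everyone else ages by one.
7. **Pruning** (PGSOM): neurons with age strictly greater than `M` are
   removed. Holes are allowed; the map may fall apart into disconnected
   islands, which is expected — the deleted neurons sit in transition
   regions between activity patterns.

New-neuron weights are interpolated from a snapshot of the pre-growth map:
linear extrapolation `2*w_winner - w_opposite` when the slot opposite the new
position is occupied, otherwise the midpoint with the winner's lowest-id
occupied neighbor, otherwise (a lone neuron) the winner's weight plus a
seeded perturbation within 1% of the per-dimension data range. Snapshot
semantics make a multi-slot growth event order-independent.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sf` | 0.8 | spread factor in (0,1); `GT = -D ln(sf)`, so larger values ease growth |
| `rf` | 1.5 | age threshold as a multiple of the batch size: `M = round(rf * batch_size)` |
| `eta0` | 0.3 | initial learning rate |
| `r` | 1.0 | decay constant in the factor `1 - r/|Phi|` |
| `eta_decay` | `"iteration"` | decay cadence (see below) |
| `tau` | `NULL` = D | damping scale of the neighbor update (see below) |
| `batch_size` | 4000 | samples presented per training iteration |
| `max_iter` | 50 | training iterations |
| `calib_size` | 2000 | labeled samples for neuron calibration |

The defaults mirror the protocol the method was developed under: batches of
4000 from a ~7700-sample pool, 50 iterations, 2000 calibration samples, and
the best-performing cell of the SF x RF grid (0.8, 1.5).

### Decay cadence

The decay factor `1 - r/|Phi|` ties the decay speed to the network size.
Applied after every *sample*, it collapses `eta` to the floor within a few
dozen presentations while the map still has 4 neurons (the factor is 0.75),
and the frozen map then degenerates: a single dominant winner becomes
enclosed by its own children and the network stalls at ~6 neurons. Applied
once per training *iteration* — the reading consistent with a batch
protocol in which the learning rate "decreases as iterations advance" — the
map grows into the hundreds-to-thousands of neurons the method is known
for. The cadence is therefore a config switch, `eta_decay`, defaulting to
`"iteration"`; `"presentation"` gives the literal per-sample reading.

### Neighbor damping `tau`

The damping $e^{-d_i}$ compares a *summed* squared distance, which is
$O(D)$: at $D = 101$ on standardized features $d_i \approx 100\text{–}400$
and the factor underflows to zero, silently disabling the whole
neighborhood update. `tau = NULL` (the default) resolves to $D$ at training
time, so the exponent is the mean per-dimension squared distance — invariant
to dimensionality and identical to the plain form at $D = 1$. Any explicit
numeric `tau` is honored.

### The undefined decay constant `r`

`r` has no published definition beyond its role in the factor
`1 - r/|Phi|`; it is housed as a config constant with default 1.0 rather
than guessed at. Note that with `r = 1` and a map of ~1000 neurons the
per-iteration decay is only 0.1% — the learning rate is effectively
constant, and convergence comes from the growth/pruning balance, not from
annealing.

## Feature pipeline

Raw logs are 30 Hz, 7 channels (wrist x/y/z, hip x/y/z, abdominal piezo).
Non-overlapping 500-sample windows (the stride is exposed; overlap in the
original protocol is unstated) are extended with two synthetic acceleration
magnitudes $\sqrt{x^2+y^2+z^2}$ (wrist and hip), giving 9 signals. Eleven
statistics per signal — mean, variance, RMS, kurtosis, skewness, energy,
and the 10/25/50/75/90 percentiles — plus the two Pearson correlations of
the synthetic signals with the piezo channel give $11 \times 9 + 2 = 101$
features.

Statistic conventions are pinned because the names alone are ambiguous:
population variance (divide by $n$), Fisher *excess* kurtosis (normal
$\to 0$), Fisher–Pearson $g_1$ skewness, energy as the mean of squares
(scale-free in the window length; the plain sum is config-selectable),
percentiles by linear interpolation between order statistics, and
correlations defined as 0 for constant series. Constant signals get
kurtosis and skewness 0. The test suite cross-checks every statistic
against independent implementations.

Feature scaling is deliberately outside the training core (`standardize()`
provides train-statistics z-scoring), because the winner search and the
damping are scale-sensitive and scaling policy belongs to the pipeline.

## Synthetic data

The study's dataset is not public, so the generator reproduces the
*structure* the method assumes: nine classes with the study's imbalanced
proportions (1635, 807, 794, 840, 1549, 1646, 494, 359, 462 of 8586),
isotropic unit-variance Gaussian clusters in 101 dimensions, centroids
drawn on a sphere of radius `separation` (default 8 within-class standard
deviations), and one deliberately overlapping pair — classes 4 and 6,
emulating the walking vs low-speed-running confusion — pulled to
`separation/4` apart. Class sizes follow largest-remainder rounding, which
is deterministic and within one sample of exact proportionality. A
raw-signal generator (class-specific sinusoids, 0.5–4 Hz, plus Gaussian
noise) exercises the feature pipeline end to end.

What passing tests on this generator do **not** show: real accelerometry is
non-Gaussian, non-stationary, and correlated across channels; per-subject
variation, sensor drift, and transitional movements are absent. The
generator validates the *mechanics* (growth, pruning, calibration,
evaluation) and the qualitative behaviors, not field performance.

## Numerical choices

* Winner search uses the norm expansion
  $\lVert x\rVert^2 - 2x\cdot w + \lVert w\rVert^2$ (a single BLAS product
  against all neurons, with cached $\lVert w\rVert^2$), then recomputes the
  distance exactly for near-minimal candidates, so reported distances are
  exact and ties resolve to the lowest neuron id.
* Neurons live in preallocated capacity-doubling arrays in id order; free
  columns carry squared norm $\infty$ so the vectorized search can ignore
  them. A lattice index (position to slot) is rebuilt after pruning.
* CEQ conservation under interior redistribution holds to 1e-9 relative
  (tested over 1000 random events).
* `M = round(rf * batch_size)` rounds half-up.
* Degenerate guards: pruning never empties the network (the youngest neuron
  survives, with a warning); `r >= |Phi|` clamps the learning rate to
  `eta_min` with a warning; batches larger than the pool sample with
  replacement.
* Desk-scale protocol used by the property checks: 2000 samples, batches of
  1000, 10 iterations, 500 calibration samples — the full protocol scaled
  by ~1/4 with the calibration ratio preserved.

## Known limitations

* **Pruning does not make the map smaller here.** Intuition says a pruned
  run can only remove neurons relative to an unpruned run. Dynamically that
  is false: pruning frees lattice slots, which turns enclosed interior
  winners back into boundary winners, and in the operating regime
  ($\eta \cdot \bar d$ at or above $GT$) freed slots refill immediately. In
  our measurements the pruned map ends a few percent *larger* than the
  growing-only map at equal seeds, while matching or beating its accuracy
  with the same-order neuron count. Pruning's documented benefits — escape
  from topological stalls, adaptation to drift, removal of stale transition
  neurons — are real; a guaranteed size reduction is not one of them.
* **The overlapped pair caps accuracy.** With the default generator the
  overlapping pair sits $2\sigma$ apart and holds 29% of the mass; the
  per-sample error of an ideal midpoint rule on that pair is
  $\Phi(-1) \approx 15.9\%$, putting even a perfect nearest-centroid
  classifier near 95% overall. A winner-take-all map labeled by a
  2000-sample majority vote spreads those samples over hundreds of neurons
  (one to two votes each in the overlap region), which costs several more
  points: the end-to-end runs land at 88–92%, essentially all errors inside
  the designed pair. This mirrors the behavior the method reports on real
  data, where the same activity pair dominates the confusion matrix.
* Training is single-threaded and presentation-sequential by design (the
  algorithm is inherently online); the full protocol (two 200k-presentation
  runs) takes a few minutes on one CPU.
* Calibration is hard majority voting; no soft labels, no rejection option
  for far-from-map samples.

## Worked example

```{r example}
library(pgsom)

d <- make_feature_dataset(synth_config(seed = 1))
sp <- split_train_validation(nrow(d$x), seed = 1)

cfg <- train_config("pgsom", sf = 0.8, rf = 1.5, seed = 1)
net <- train_network(d$x[sp$train, ], cfg)

set.seed(10001)
ci <- sample(sp$train, 2000)
labels <- calibrate(net, d$x[ci, ], d$y[ci])
ev <- evaluate_model(net, labels, d$x[sp$validation, ], d$y[sp$validation])
ev$accuracy
ev$confusion
```
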