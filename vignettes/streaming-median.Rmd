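---
title: "Memory-less streaming median estimation: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-less streaming median estimation: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmedian)
```

## The estimator

Threshold-based spike detection needs a running estimate of the noise floor
of an extracellular recording, and the robust way to get one is through the
median.  The classical moving median (CMM) keeps the last $L$ samples
(with $L = 2m + 1$ odd) and reports the exact median of that window; it
needs both the sample values and their arrival order, because the oldest
sample is the one evicted.

The memory-less estimator (NM) implemented here drops the arrival-order
bookkeeping entirely.  It keeps a single always-sorted buffer of length $L$
whose central element $x_{m+1}$ is the estimate, and on each new sample $x$:

* $x < x_{m+1}$: insert $x$ in sorted order in the lower half and drop the
  buffer **maximum**;
* $x > x_{m+1}$: insert in the upper half and drop the buffer **minimum**;
* $x = x_{m+1}$: place $x$ at the centre and drop the first or last element
  according to an alternating tie bit $S$, which then flips.

Eviction by buffer position rather than age makes the buffer contract
around the median: extremes are always the first to go, so after a few
buffer cycles the contents are concentrated near the estimand
(see `buffer_density()`).  The estimate is unbiased for any unimodal input:
if the central value sits below the true median, more than half of the
incoming samples fall above it and push it back up, and symmetrically from
above — a restoring drift with equilibrium exactly at the point where half
the probability mass lies on each side, in the manner of diffusive flux
across a membrane.  The price is inertia: after a genuine change in the
input distribution the concentrated buffer must be displaced sample by
sample, so NM settles more slowly than a CMM of the same length.  The
package quantifies both sides of that trade.

Properties asserted by the test suite rather than argued here: the buffer
is non-decreasing after every update; the estimate is bounded by the data
seen so far; the mean estimation error on i.i.d. Gaussian and Beta input is
zero within Monte-Carlo error; an extreme outlier injected into a converged
buffer survives $k$ further median-symmetric samples with probability
$2^{-k}$ (each step evicts one of the two extremes with equal chance).

## Hardware cell model

The estimator exists because this insertion rule maps onto a linear array
of identical register–comparator–multiplexer cells: each cell compares its
register $R_i$ with the new sample ($C_i = 0$ iff $R_i \le X$) and either
keeps its value, takes $X$, or takes a neighbour's register; the central
cell's three-way comparator ($X < M$, $X = M$, $X > M$) selects which half
shifts.  `hw_cell_step()` models that array at truth-table level — each
register assignment is computed from the comparator signals exactly as the
combinational logic would — and the suite drives it in lockstep with
`nm_update()` for $10^4$ steps on tie-rich integer streams, requiring
bit-identical buffers throughout.  This is a genuine dual route: the two
implementations share no code.

The same sorted-buffer primitive composes into a quartile cascade
(`quantile_cascade_run()`): a primary estimator tracks the median and two
secondary instances receive only the samples below (respectively above) the
primary's estimate, so their centres track the first and third quartiles.
Samples exactly equal to the primary estimate are routed by the primary's
tie bit; the choice is arbitrary but must be fixed, and the alternating bit
keeps the two sides balanced.

## Noise sigma and spike detection

For Gaussian noise $x \sim N(0, \sigma^2)$ the rectified signal $|x|$ is
half-normal with median $\sigma\,\Phi^{-1}(3/4) = 0.6745\,\sigma$, so
$\hat\sigma = \mathrm{median}(|x|)/0.6745$ (`sigma_from_median()`; the
constant is $\sqrt{2}\,\mathrm{erf}^{-1}(1/2)$, 0.675 to the precision it
is usually quoted at).  `streaming_threshold()` feeds $|x|$ — not $x$ — to
the configured estimator and returns $K\hat\sigma$ per sample, $K = 4$ by
default.  Spikes barely perturb this estimate because they occupy a tiny
fraction of samples and the median ignores them; that is the point of the
whole construction.

Event extraction (`detect_crossings()`) is deliberately plain: an event
opens when the polarity-transformed trace first exceeds the running
threshold, is localised at the most extreme sample before re-crossing, and
further events are suppressed for a refractory gap (default 30 samples,
about 1 ms at 30 kHz).  Extracellular spikes are negative-going, so the
default polarity applies $-K\hat\sigma$ to the raw trace.

## Synthetic data

No external recordings are used; every experiment input comes from a
seeded generator with exact ground truth:

* `gen_step_stream()` — i.i.d. draws switching distribution at a known
  sample; true medians come from quantile functions (e.g. Beta(1.5, 4) has
  median 0.2439, Beta(4, 1.5) has 0.7561, $|N(0,1)|$ has 0.6745).
* `gen_spiky_signal()` — Gaussian noise with biphasic templates (1.2 ms at
  a nominal 30 kHz, sharp negative lobe, slower rebound) planted at random
  positions with a minimum gap of one template width and peak amplitude
  $\mathrm{SNR}\times\sigma$; planted indices are returned as ground truth.
* `gen_outlier_mixture()` — $(1-p)\,N(0,1) + p\,N(0,10)$ with $p = 0.05$
  by default; the contamination parameters are a documented package default
  (the robustness comparison needs *some* concrete heavy-tail stand-in) and
  are fully configurable.

These streams emulate the statistical structure the estimators care about
— median level, dispersion, contamination, spike sparsity — and nothing
else.  Real recordings add 1/f background, electrode drift, bursting and
overlapping units; passing tests here say the estimator mathematics is
right, not that detection performance on any particular preparation is
guaranteed.

## Experiment operationalisations

Several quantities the package reports require conventions the underlying
characterisations leave open; they are fixed here once and used everywhere.

**Settling time.**  After a median step $\mu_i \to \mu_f$, settling is the
first post-step sample at which the estimate touches
$\mu_f - 0.05\,(\mu_f - \mu_i)$, direction-aware.  First touch is used
(not sustained crossing) because trajectories are noisy; with any
sustained-crossing rule the measured time would depend on an arbitrary
dwell parameter.  Step experiments run $10L$ pre-step samples (so the
estimator is past its transient) and $20L$ post-step samples per
repetition.

**Steady state.**  Dispersion on stationary input is the standard
deviation of the estimate pooled over the window $(10L, 20L]$ across
repetitions (`steady_state_std()`).  The NM buffer keeps concentrating
slowly for a long time, so "the" variance depends on this window; pinning
it to the decade after the initial transient is the convention used for
every equal-variance pairing quoted by the package (NM-63 pairs with
CMM-511 under it).  `error_distribution()` is the other, simpler summary —
the final estimate of each repetition — and is what the step-change error
histograms use.

**ROC for small changes.**  To ask how well an estimator *discriminates* a
small median change, each repetition contributes its estimate at the end of
a pre-change segment ($50L$ samples from $N(\mu_0, (c\mu_0)^2)$,
$\mu_0 = 1$, $c = 0.25$) and at the end of a post-change segment ($30L$
samples at $\mu_0(1+\delta)$).  Sweeping a decision threshold over the two
estimate populations gives the ROC; the area under it is computed by the
Mann–Whitney rank statistic.  The decision statistic — the estimator output
itself — and the segment lengths are package choices: the characterisation
being reproduced shows the pre/post estimate distributions but does not
name the classifier.  A lower-variance estimator separates the two
populations at smaller $\delta$; at $\delta = 0$ any correct construction
must give AUC $= 1/2$, which the tests check.

**Repetition counts** default to desk scale (hundreds to 5,000 where the
full characterisations used $10^4$–$10^5$); every driver takes `n_reps`
and a seed, and the acceptance script states the sizes it uses.

## Numerical choices

* **Tie detection is exact binary equality** with the central value, as a
  hardware comparator would decide it.  An epsilon band would bias the
  drop side for continuous input and change nothing for the discrete
  inputs where ties actually occur.
* **Insertion is upper-bound** (after any equal values) on both halves,
  matching the comparator convention $C_i = [R_i > X]$; the resulting
  multiset is the same under any stable rule, but buffer states must be
  bit-identical for the hardware lockstep check, so the rule is fixed.
* **CMM eviction** removes one instance of the oldest value; since the
  window is a multiset, which equal instance goes is unobservable in the
  median.
* **Warm-up**: before $L$ samples have arrived both estimators keep a
  growing buffer and report its middle element, lower-middle on even
  counts.  The full-buffer regime is exactly reproduced once sample $L$
  arrives.
* **Non-finite samples are errors**, not data: NaN breaks the total order
  the sorted buffer relies on, and silently ordering infinities would
  poison the buffer for $O(L)$ steps.
* The tie bit defaults to a deterministic alternating bit; a seeded random
  mode (`tie = "random"`) is available where the randomised reading of the
  tie rule is wanted.  Both are unbiased; the alternating bit is what the
  hardware uses and is reproducible without an RNG.

## Known limitations

* NM settling after a step is heavy-tailed: for a large folded-normal
  median step the typical (median) repetition settles within $L$–$2L$
  samples, but the mean is ~15% above $2L$ because the 95% settling level
  sits near the median of the post-step distribution, where the approach is
  diffusive rather than ballistic.  Summaries report means; interpret them
  with the tails in mind.
* The steady-state variance advantage depends on the measurement window
  (see above); quoting a single ratio without the window convention is not
  meaningful.
* `detect_crossings()` is a detector, not a sorter: overlapping units,
  bursts, and waveform clustering are out of scope.
* The generators draw i.i.d. samples; none of the drivers characterise
  autocorrelated noise.
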