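# nmedian

Streaming median estimation for real-time spike detection in extracellular
neural recordings.

Threshold-based spike detection sets its threshold at `K·σ_noise`, and the
robust way to estimate `σ_noise` online is through the median of the
rectified signal: for Gaussian noise, `σ = median(|x|) / 0.675` (the
constant is `√2·erf⁻¹(1/2) = Φ⁻¹(3/4) = 0.6745`).  The bottleneck is the
streaming median itself.  The classical moving median (CMM) of a window of
length `L = 2m+1` needs the arrival order of every sample so it can evict
the oldest one.

This package implements a **memory-less** alternative (NM): a single
always-sorted buffer whose central element `x_{m+1}` is the estimate.  Each
new sample `x` is inserted at its sorted position and an extreme is
dropped —

* `x < x_{m+1}`: insert left, drop the **maximum**;
* `x > x_{m+1}`: insert right, drop the **minimum**;
* `x = x_{m+1}`: insert at the centre; an alternating bit `S` picks the
  dropped extreme.

Eviction by position instead of age needs no arrival-time bookkeeping and
makes the buffer concentrate around the median, cutting the estimator
variance roughly eight-fold at equal `L` (an NM-63 buffer matches a
CMM-511), at the cost of about twice the settling time of a CMM of the same
length after a genuine median change.  The package includes the CMM
baseline, a truth-table model of the hardware sorting-cell array (verified
in lockstep against the algorithm), a quartile cascade, noise-sigma
estimation and threshold-crossing spike detection, synthetic generators
with exact ground truth, and the simulation drivers that characterise
variance, settling time, buffer density dynamics, small-change ROC
discrimination and outlier robustness.

## Worked example

The insertion rules on a buffer of length 7 (`L = 7`, centre = 4th
element):

```r
library(nmedian)
s <- nm_init(1:7)      # sorted buffer 1 2 3 4 5 6 7, estimate 4
s <- nm_update(s, 2)   # 2 < 4: inserted left, maximum 7 dropped
s$values               # 1 2 2 3 4 5 6
nm_estimate(s)         # 3
s <- nm_update(s, 4)   # 4 > 3: inserted right, minimum 1 dropped
nm_estimate(s)         # 4
```

Spike detection on a synthetic recording (Gaussian noise `σ = 1`, 60
biphasic spikes planted at SNR 8, i.e. peak depth 8σ):

```r
sig <- gen_spiky_signal(spike_train_spec(n_samples = 30000, noise_sigma = 1,
                                         snr = 8, spike_rate = 2, seed = 1))
ev <- detect_spikes(sig$samples, threshold_config(K = 4, L = 63))
head(ev, 3)
#>   index      peak threshold
#> 1  1833 -8.851344  4.234819
#> 2  1870 -8.182224  4.678551
#> 3  2378 -8.562550  4.328202
```

58 of the 60 planted spikes are recovered within ±3 samples (61 events
total).  The running threshold averages 4.23 — `K = 4` times the estimated
noise sigma, slightly above 4.0 because the planted spikes occupy ~7% of
the samples and nudge the median of `|x|` upward; that robustness to sparse
large excursions is exactly why the median is used.

The variance advantage at equal buffer length, on i.i.d. `N(0, 1)`:

```r
s_nm  <- steady_state_std(dist_normal(0, 1), L = 63, backend = "nm",
                          n_reps = 300, seed = 2)   # 0.0517
s_cmm <- steady_state_std(dist_normal(0, 1), L = 63, backend = "cmm",
                          n_reps = 300, seed = 2)   # 0.1565
(s_cmm / s_nm)^2                                    # 9.16
```

## Command line

A thin wrapper is installed at
`system.file("cli", "nmedian", package = "nmedian")`:

```sh
nmedian generate --type spiky --n 30000 --snr 8 --seed 1 --out sig.csv
nmedian detect --k 4 -L 63 --refractory 30 --out events.csv sig.csv
nmedian estimate -L 63 --backend nm --out medians.csv sig.csv
nmedian simulate step --reps 500 --seed 1 -L 63 --backend nm --out step.csv
```

Signals are CSV (`index,value`) or raw little-endian int16 with a JSON
sidecar (`{"sample_rate": ..., "scale": ...}`); events are CSV
(`index,peak,threshold`).  CLI output is byte-identical to the
corresponding library calls.

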