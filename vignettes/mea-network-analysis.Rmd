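---
title: "MEA network activity analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEA network activity analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meaflow)
```

meaflow analyses spontaneous activity of cultured neuronal networks
recorded on multi-well microelectrode arrays (MEAs): multichannel
extracellular voltage traces sampled at 12.5 kHz from wells of 16 or 64
electrodes, typically in 10-minute sessions. The pipeline turns raw
traces into spike trains, spike trains into bursts and synchrony
measures, and those into a per-well feature vector suitable for
comparing network phenotypes — for example human pluripotent stem cell
(hPSC) derived cortical networks against embryonic rat cortical
cultures. This vignette explains each stage's model, its tunable
parameters, and the design decisions behind them.

## Consensus spike detection

Extracellular spikes in hPSC-derived cultures are often small relative
to the noise floor, so the detector combines two methods and keeps only
events on which they agree.

1. **Prefilter.** A zero-phase elliptic bandpass, 200–3000 Hz, order 4,
   0.1 dB passband ripple, 40 dB stopband attenuation, applied
   forward–backward (`bandpass_filter()`). The band edges are the
   analysis passband; the remaining filter parameters are free design
   choices, chosen so a 1 kHz tone passes within 5% while 10 Hz and
   mains components are suppressed below 10^-3^.
2. **Noise estimate.** `estimate_noise_sd()` uses the robust estimator
   σ̂ = median(|x|)/0.6745, computed on the *filtered* trace (the
   threshold is applied there). Unlike the plain SD, σ̂ moves by less
   than 5% when 1% of samples are replaced by 20 σ spikes.
3. **Amplitude threshold.** Local extrema of |x| exceeding k σ̂ with
   k = 4.5, thinned to a 1 ms dead time (larger extremum wins). The
   default polarity is `"both"` because extracellular spikes are
   biphasic; `"neg"` is available by configuration.
4. **SWTTEO.** A stationary (undecimated) wavelet transform with the
   sym2 wavelet; the Teager energy operator
   ψ(n) = d(n)² − d(n−1)d(n+1) applied to the detail coefficients,
   rectified, smoothed with a 25-sample (2 ms) Hamming window and
   summed across levels. The detector extracts as many top energy peaks
   as the amplitude threshold produced candidates, coupling the two
   methods (`swtteo_select()`).
5. **Consensus.** Greedy in-order one-to-one matching within ±1 ms;
   kept spikes take the threshold detector's timestamp.

**Decomposition depth.** The default is `level = 3`. At 12.5 kHz the
level-1 and level-2 detail bands (≈1.6–6.2 kHz) contain mostly noise,
while the energy of a ~1 ms biphasic spike concentrates in the level-3
band (≈0.8–1.6 kHz). With level 2 the top-N energy peaks are dominated
by satellite and noise maxima and consensus sensitivity on synthetic
ground truth drops from 0.98 to ≈0.71. The level, wavelet and smoothing
window are all configuration keys.

**Top-N coupling.** "The candidate count is fed to the wavelet
detector" admits two readings — top-N energy peaks, or an energy
threshold calibrated to yield N events. meaflow implements top-N with a
dead time; with well-separated peaks the two are equivalent.

**False positives on pure noise.** For stationary Gaussian noise in a
200–3000 Hz band, Rice's formula puts the rate of |x| excursions above
4.5 σ at roughly 5 per minute. Both detector branches respond to the
same large-amplitude excursions, so the consensus rate on noise-only
traces is not the product of two independent error rates; empirically it
is ≈0.8–1.0 events/min/electrode with the default two-sided polarity
(about half that with `polarity = "neg"`). The active-electrode rule
(>10 spikes/min) keeps such electrodes out of downstream analysis.

**Active electrodes.** An electrode is active iff it fires *strictly*
more than 10 spikes per minute; an electrode at exactly 10/min is
inactive. Only active electrodes enter MFR, burst and synchrony
summaries.

## logISI burst detection

Bursts are detected per electrode from the histogram of log~10~
inter-spike intervals (10 bins per decade, lowess-smoothed over roughly
a 5-bin span). If a peak exists below 100 ms (the intra-burst mode), the
histogram minimum between it and a later peak is scored with the void
parameter v = 1 − h~min~/√(h~peak1~ h~peak2~); the first valley (in ISI
order) with v ≥ 0.7 sets the burst threshold ISITh.

Three details are deliberate:

- **Valley choice.** Scanning later peaks in ISI order and taking the
  first valley that passes the void gate keeps ISITh near the intra-burst
  mode; selecting the *deepest* valley instead can latch onto tiny
  ripples in the histogram tail and produce thresholds of several
  seconds. A flat minimal region is resolved to its middle bin.
- **Intra-peak floor.** A candidate intra-burst peak must reach at
  least 10% of the tallest peak. Without this, 1–2-count ripples below
  100 ms in an exponential (tonic, non-bursting) ISI histogram pass the
  void test against the main mode and invent a threshold.
- **No fallback.** When no valley qualifies, the electrode is treated
  as non-bursting and contributes no bursts (no maximum-ISI fallback).

Given ISITh, bursts are maximal runs of spikes with consecutive ISIs ≤
ISITh when ISITh ≤ 100 ms. For larger thresholds, cores are runs with
ISI ≤ 100 ms, extended at both edges across ISIs ≤ ISITh (equivalently:
a maximal ≤-ISITh run counts only if it contains a core ISI). Runs with
fewer than **5 spikes** are discarded. When ISITh < 100 ms, consecutive
bursts separated by less than **100 ms** are merged (spike counts
summed) — 100 ms acts as the minimum time between distinct bursts. The
merge is idempotent and conserves spikes-in-burst counts.

Per-electrode features: bursts/min; median burst duration; median
spikes per burst; median spike frequency in burst, by default the
ISI-based rate (n−1)/duration (configurable to n/duration); and the
percentage of the electrode's spikes inside bursts. Durations are
floored at one sample period (80 µs) before division. Well-level values
are medians across *bursting* electrodes (median-of-electrode-medians,
not pooled over bursts — the two readings differ and the per-electrode
reading matches per-well reporting of distributions).

## Synchrony and functional connectivity

**STTC.** The spike time tiling coefficient with Δt = 50 ms:
T~X~ is the fraction of the recording tiled by ±Δt windows around X's
spikes (computed exactly by merged-interval union, O(n log n)), P~X~ the
fraction of X's spikes within Δt of the other train, and
STTC = ½[(P~A~−T~B~)/(1−P~A~T~B~) + (P~B~−T~A~)/(1−P~B~T~A~)]. A term
with zero denominator is dropped; empty trains give an undefined value.
The well summary is the median over electrode pairs (mean by
configuration) — the per-pair distribution is skewed, and the median
matches box-plot-style reporting.

**CorSE.** Correlated spectral entropy: each channel's trace is cut
into 1 s Hann-tapered windows with 50% overlap; per window the
periodogram restricted to 200–3000 Hz is normalised to a probability
distribution and its Shannon entropy divided by log N~f~, giving a
series in [0, 1] (0 = pure tone, 1 = flat spectrum; an all-zero window
is assigned 1). The connectivity strength of a channel pair is the
magnitude of the Pearson correlation of their entropy series, without
detrending. Entropy is scale-free, so CorSE is invariant to per-channel
gain. Network bursts change the spectral shape of every participating
channel simultaneously, which is what the correlation picks up. CorSE
runs on the bandpassed traces by default (configurable), since the
entropy band equals the analysis passband. Pairs with CorSE > 0.7 form
the thresholded connectivity map; the well's overall strength is the
mean over all defined pairs.

## Feature vector and PCA

Per well and timepoint, seven features: mean firing rate over active
electrodes (active-only, consistent with the active-electrode rule),
bursts/min, burst duration, spike frequency in burst, spikes in burst,
percentage of spikes in bursts, and the STTC well summary. Samples with
any missing feature (e.g. no bursting electrode) are dropped with a
message. Features are standard-score normalised using the population SD
(divide by n; the sample SD is a configuration option) and decomposed
by eigendecomposition of the covariance — on z-scored data this is the
correlation-matrix PCA. All decompositions are pooled across groups and
timepoints into a single component space. Component signs are fixed by
making each component's largest-magnitude loading positive, so scores
and plots are reproducible. Explained-variance percentages are reported
for all components and sum to 100.

Group segregation is quantified by the mean silhouette width of the
labelled samples in the first three component coordinates (1 = compact,
separated groups; ≈0 = arbitrary labels; singleton groups score 0), and
assessed against a label-permutation null.

Pharmacology experiments are summarised by
`percent_change(baseline, treatment)` = 100 (treatment − baseline) /
baseline per well, e.g. −100 for complete silencing; non-positive
baselines give an undefined value.

## The synthetic-data generator

No recordings ship with the package, so every stage is validated
against `simulate_trains()` + `synthesize_raw()` ground truth:

- **Network bursts.** Onsets follow a renewal process: exponential
  inter-onset gaps plus a hard dead time of burst duration + 0.4 s,
  with the mean inter-onset interval equal to the requested burst rate.
  A memoryless (Poisson) onset process was considered and rejected: it
  places >10% of burst pairs closer than the burst duration, so
  generated "bursts" overlap and the nominal burst rate is not
  recoverable even in principle by an ISI-based detector. The dead time
  is the simplest modification that keeps bursts distinct,
  non-overlapping events while preserving the exact rate.
- **Participation and jitter.** Each electrode joins a network burst
  with probability 0.95 and its onset is shifted by a Normal(0, jitter)
  offset. Within a burst the electrode fires as a homogeneous Poisson
  process (homogeneity keeps the expected spikes-per-burst analytic);
  an independent tonic Poisson background runs throughout; trains are
  thinned to a 1 ms refractory period.
- **Raw traces.** Each spike inserts a biphasic template (unit negative
  peak, ~1.6 ms support) aligned trough-on-sample, scaled by a
  log-normal amplitude (positive, heavy-tailed, CV 0.2 by default), in
  white Gaussian noise with optional 50 Hz mains.

Two presets encode the phenotypes at their activity peak:
`hPSC_peak` (11 bursts/min, 0.7 s bursts, intra-burst rate
34/0.7 ≈ 48.6 Hz so bursts average 34 spikes, tonic 0.6 Hz, jitter
20 ms) and `rat_peak` (15 bursts/min, 0.3 s, 100 Hz ≈ 30 spikes/burst,
tonic 0.3 Hz, jitter 10 ms). The reference medians these presets mirror
are not mutually consistent to the last digit (34 spikes over 0.7 s is
48.6 Hz, while the hPSC in-burst frequency median is below 40 Hz); the
presets prioritise spikes-per-burst and duration. Participation 0.95
keeps the per-electrode burst rate close to the network rate; the tonic
rates reproduce the direction of the published difference in the
percentage of spikes in bursts (rat higher, hPSC with substantial
between-burst spiking). Zero mean inter-electrode propagation delay is
assumed (jitter only).

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: non-stationary development across
days, within-burst rate decay, electrode-specific amplitudes and noise,
correlated (shared) noise across electrodes, bursts with sub-network
structure, and electrode drift. Detection metrics on this ground truth
are an upper bound on real-data performance.

## Numerical choices and degenerate inputs

- Spike times are stored in seconds with 6 decimals (1 µs; lossless for
  an 80 µs sample period); intervals are half-open [t_start, t_end);
  all time coordinates are 0-based seconds from recording start.
- Raw traces are stored as float32 µV in a single-file container (one
  JSON header line — sampling rate, units, electrode identities —
  followed by the little-endian float32 trace matrix); readers validate
  and never repair.
- An all-zero trace has σ̂ = 0 (with a warning) and detects nothing; a
  zero-power spectral window has entropy 1; constant entropy series
  give undefined CorSE; zero-variance features abort the z-score with
  the feature named; rank-deficient PCA returns the achievable number
  of components with a warning.
- With fixed seeds every simulation, detection and pipeline output is
  bit-reproducible; pipeline runs write a manifest with content hashes
  of every output.

## Validation problem sizes

The test-suite checks run at the following scales, chosen to exercise
the study's recording geometry while keeping the suite fast: detection
ground truth on a 16-electrode, 600 s well (12.5 kHz); noise-only false
positives on 2 electrodes × 600 s; STTC against a brute-force oracle on
500 random train pairs (≤30 spikes); burst detection against an
exhaustive-scan oracle on 300 random trains (≤50 spikes); CorSE null on
50 pairs of independent 60 s noise channels; phenotype separation on
two simulated 12-well plates × 3 timepoints per phenotype at 600 s,
spike-train level. `scripts/acceptance.R` re-runs the same computations
from scratch and writes the measured values as JSON.

## Known limitations

- The logISI histogram needs enough ISIs to be stable; below a few
  hundred spikes the void test can misfire, which is why weakly active
  electrodes should be filtered by the activity rule first.
- CorSE window/overlap defaults (1 s, 50%) bound the temporal
  resolution of the entropy series; bursts shorter than ~0.2 s blur
  into single windows.
- The consensus detector's noise-only false-positive rate (≈1/min with
  two-sided polarity) exceeds what two independent detectors would
  give, because both branches respond to the same amplitude excursions;
  see the detection section.
- No spike sorting is performed; multi-unit electrodes are analysed as
  single trains.
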