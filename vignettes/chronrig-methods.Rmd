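---
title: "Models and methods behind chronrig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronrig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronrig)
```

chronrig is the computational companion of a millisecond-precise rodent
behavior rig. Three problems recur in such rigs, and the package addresses
each with a small, testable model: (1) how event-timing noise corrupts
event-aligned spike analyses; (2) how to equalize auditory stimuli to a
target sound pressure level through an uncalibrated playback chain; and
(3) how to characterize and compensate the delays between a command pulse
and the physical delivery of a stimulus or reinforcer. This vignette states
the models, the defaults and why they were chosen, and what the synthetic
generators do and do not capture.

## 1. Event-timing noise and event-aligned analysis

### Generative model

A session of duration $T$ contains $n$ reference events (cue onsets). The
*true* event train is either periodic with interval $\Delta t$ or
uniform-random with a minimum spacing. The *observed* train — what a
behavior-control system actually logs — is the true train plus i.i.d.
Gaussian timing noise of standard deviation $\sigma_j$ (the jitter), then
re-sorted. Spiking is the union of two point processes:

* **evoked spikes**: each event contributes $k \sim \mathrm{Poisson}(\mu_k)$
  spikes at latencies drawn from
  $\mathcal{N}(\mu_\ell, \sigma_\mathrm{bio}^2)$ after the *true* event
  time;
* **background spikes**: a homogeneous Poisson process of rate $\lambda$.

Aligning the spikes to the *observed* events — the only option an
experimenter has — smears the evoked response: each relative spike time is
a latency draw minus an independent jitter draw, so the peri-event time
histogram (PETH) peak has width

$$\sigma_\mathrm{PETH} = \sqrt{\sigma_\mathrm{bio}^2 + \sigma_j^2}.$$

This quadrature law is the quantitative content of the toolkit's central
claim: unobserved event-timing noise is mathematically inseparable from
biological latency variability, and it is verified by `fit_gaussian()`
recovering $\sqrt{\sigma_\mathrm{bio}^2+\sigma_j^2}$ within 10% on
500-event simulated sessions.

### Defaults

No canonical parameter set exists for this kind of simulation, so the
defaults of `simulation_config()` were chosen once to give a clearly
resolvable response at desk scale and are all overridable: a 600 s session,
100 periodic events at 5 s intervals, evoked latency 50 ± 10 ms, a mean of
3 evoked spikes per event, and 5 Hz background firing — firing rates and
latencies typical of cortical and basal-forebrain units in head-fixed
preparations. The per-event evoked count is Poisson because spike counts in
short windows are approximately Poisson-dispersed; a fixed-count mode
exists for deterministic limit tests.

Two boundary policies matter and are deliberate:

* jittered events leaving $[0, T]$ are clamped to the session bounds (and
  counted), so the trial count of trial-wise analyses is preserved;
* evoked spikes leaving $[0, T]$ are dropped (and counted), because a spike
  outside the recording simply does not exist in the data.

All times are seconds in double precision; every binning operation uses
half-open bins $[\mathrm{left}, \mathrm{right})$, so a spike on a bin edge
belongs to exactly one bin.

### PETH and Gaussian fit

`align_spikes()` collects relative times in a window (default
$[-0.5, 0.5)$ s) around each event; a spike can enter several overlapping
windows. `compute_peth()` bins at 10 ms by default and normalizes to a
trial-averaged rate in Hz; a truncated final bin is dropped with a warning
rather than silently producing a thin bin. `fit_gaussian()` fits
$r(t) = b + a\,e^{-(t-\mu)^2/2\sigma^2}$ by Levenberg–Marquardt with a
deterministic initialization ($b$ at the median rate, $a$ at max − median,
$\mu$ at the argmax bin center, $\sigma$ at twice the bin width) and box
bounds $\sigma \in (\text{bin width}/2, \text{window length})$. The
initialization is robust for unimodal PETHs, which is the intended domain;
non-convergence is reported as a flagged result so sweeps never abort.

`degradation_sweep()` repeats the whole pipeline over a grid of jitter SDs
with fresh seeds and reports the mean ± SD across seeds of a response
metric. The "cross-correlation" metric is the peak PETH rate minus the
median (baseline) rate, which equals the event–spike cross-correlation peak
up to binning constants; the fitted amplitude and the peak of the lagged
mutual information are the alternatives.

## 2. Mutual information between events and spikes

Spike trains can carry event-timing information that linear measures miss
— most strikingly, the reliable *absence* of spikes at certain lags of a
periodic schedule is itself informative. The package quantifies this with
the plug-in mutual information between two discretized sequences: the time
axis is cut into bins of width $\Delta$ (default 10 ms, matching the PETH),
$X_t$ indicates whether bin $t$ contains an event, and $Y_t$ is the spike
count in bin $t$, capped at 3 (excess lumped) to keep the alphabet small.
For a lag $\ell$ in bins,

$$I_\ell(X;Y) = \sum_{x,y} \hat p(x,y)\,
\log_2 \frac{\hat p(x,y)}{\hat p(x)\,\hat p(y)}$$

over the pairing $(X_t, Y_{t+\ell})$, positive lags pairing events with
later spikes. The plug-in estimator was chosen over adaptive or
nearest-neighbor estimators because it is transparent and exactly checkable
against hand computation; its positive bias is handled two ways:

* the first-order Miller–Madow correction, subtracting
  $(|X||Y|-|X|-|Y|+1)/(2N\ln 2)$ bits (floored at zero, raw value
  retained);
* a shuffle null (`shuffle_null()`) that recomputes the MI after circular
  shifts of the spike train by uniform random offsets. Circular shifting —
  rather than permutation — preserves the inter-spike-interval structure,
  so the null carries the same estimator bias as the observed value.

On simulated sessions the lagged MI peaks at the lag bin containing the
evoked latency, degrades monotonically with event-timing jitter, and, for
short-period schedules, shows a secondary elevation one cycle after the
response, where spiking is reliably absent relative to the cycle.

## 3. Closed-loop SPL calibration and equalized synthesis

A playback chain (sound card, amplifier, speaker, room) has a nonflat
frequency response, so equal digital amplitudes do not produce equal sound
pressure levels. The calibration loop plays a tone at amplitude $A$,
measures its level $L$ dB SPL, and updates

$$A_0 = A \cdot 10^{(L_0 - L)/20},$$

where $L_0$ is the target level. For a chain whose measured level is
linear in $20\log_{10} A$ this update is *exact in one step*; the loop
therefore offers both a single-step mode (update once, verify once) and an
iterative mode (default tolerance 0.5 dB, max 10 iterations) for chains
that are only approximately linear or have measurement noise. Re-running
the loop from a converged amplitude performs zero corrective updates.

The synthetic transducer backend stands in for the physical
speaker–microphone–analyzer chain:
$L = 20\log_{10}(A) + G(f) + \mathrm{offset}\ (+\ \text{noise})$, with a
user-supplied smooth gain curve $G(f)$ in dB. The offset defaults to 94 dB
so that full scale ($A=1$) maps to 94 dB SPL, mirroring the 94 dB = 1 Pa
convention of microphone calibrators; the real offset of any physical
chain is hardware-defined, which is exactly why the loop never needs to
know it. The backend is an S3 interface (`measure_spl()` generic), so a
hardware-backed implementation can be dropped in without touching the
loop.

Calibrated **white noise** is scaled standard normal samples
(`randn`-style), default 6 s at 44.1 kHz with pre-assigned amplitude 0.2.
Its calibrated amplitude is the *arithmetic mean of the per-anchor
amplitudes* $A_0$ at 1, 2, 5, 10 and 20 kHz — an amplitude average, not a
dB average; the two differ for nonflat chains and the amplitude-domain
average is the protocol implemented here. `synthesize_calibrated()` then
delivers any target level $L^*$ by scaling a table entry,
$A^* = A_0 \cdot 10^{(L^*-L_0)/20}$, interpolating $A_0$ linearly in log
frequency between table entries (flagged) and refusing levels that would
require $A^* > 1$. The calibrated grid defaults to 1–21 kHz at 1 kHz steps;
ultrasonic calibration is out of scope because ordinary speakers do not
play it efficiently.

## 4. Delivery-latency characterization and compensation

Every actuator (LED, sound card, solenoid valve) actuates some time after
its command pulse. The latency pipeline pairs command and actuation
timestamp streams by a greedy earliest-match within a `max_lag` window
(default 100 ms): each command takes the earliest unconsumed actuation in
$[c, c + \text{max\_lag})$. In the intended regime — one actuation per
trial, inter-command spacing larger than `max_lag` — the greedy match
coincides with the optimal assignment, and this separation condition is
documented as a precondition rather than solved with a general assignment
algorithm. `summarize_delays()` reports the matched count, sample mean,
unbiased $(n-1)$ SD (matching the mean ± SD convention of latency
reporting), extremes and interpolated percentiles.

The mean latency is a systematic offset and can be removed *post hoc*:
`compensate()` shifts command timestamps by the measured mean to estimate
delivery times. The SD — the jitter — is irreducible by any per-session
constant and is attached to the corrected times as metadata, because it is
the quantity that enters the PETH width law of section 1.

`simulate_delays()` generates fixtures: delays are zero-truncated normal
(a delay cannot be negative; truncation is by resampling and is negligible
whenever the mean exceeds a few SDs) or shifted gamma for skewed
valve-like delays, whose shape is not determinable from summary statistics
alone.

## 5. Problem sizes, tolerances and reproducibility

The test and acceptance workloads run at desk scale, chosen so the whole
suite completes in well under a minute of simulation time while keeping
every statistical check comfortably powered: width-combination checks use
500-event sessions (~14,000 spikes); degradation sweeps use 20 seeds per
jitter level over SDs of 0, 10, 50 and 200 ms; law-of-large-number checks
use $10^4$ events or draws; delay-recovery checks use the channel's actual
repeat counts (60 or 180) with a $4\,\mathrm{SD}/\sqrt{n}$ acceptance band
on the recovered mean.

All randomness flows from explicit integer seeds: every generator takes a
`seed` argument (or inherits the stream of `simulate_experiment()`'s
single config seed), identical seeds give bitwise-identical outputs, and
CLI runs write a JSON manifest containing the resolved configuration and
seed next to their outputs.

## 6. What the synthetic generators do not capture

The simulation layer is deliberately minimal: stationary rates, Gaussian
latency distributions, no refractory periods, no bursting, no rate drift,
no multi-neuron correlation structure, and Gaussian measurement noise in
the transducer. Passing tests therefore demonstrate the *analysis
machinery* — alignment, estimation, calibration algebra, pairing — under a
known generative model; they do not certify performance on real data with
non-stationary firing or non-Gaussian delays. Likewise the synthetic
transducer is memoryless and noiseless by default; distortion,
reverberation and spectral leakage of real rooms are out of scope, which
is why the backend is pluggable.
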