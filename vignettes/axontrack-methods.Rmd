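---
title: "Tracking single axonal action potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking single axonal action potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Extracellular signals of unmyelinated cortical axons on high-density
microelectrode arrays (HD-MEAs) are tiny — roughly 1 to 20 noise standard
deviations, against ~10x larger signals at the axon initial segment (AIS).
Averaging many trials reveals where an axon runs, but destroys exactly what
one wants to study: the trial-to-trial timing of individual action
potentials (APs). `axontrack` implements the alternative: build
per-electrode templates once by spike-triggered averaging, then detect each
*single* AP by matched filtering across small groups of neighbouring
electrodes, estimate its arrival time to sub-sample precision, and turn the
arrival tables into conduction statistics — velocity, jitter accumulation,
activation latency, and activity-dependent slowing.

Because no public recordings accompany this problem setting, the package
ships a synthetic HD-MEA generator with complete ground truth. All
quantitative claims made by the test suite are claims about that generator;
they are listed at the end together with what they do and do not show about
real recordings.

## The synthetic recording model

**Geometry.** Electrodes form a regular grid (`build_array()`), 17.8 um
center-to-center by default, matching arrays with ~3150 electrodes/mm^2. An
axonal arbor (`arbor_model()`) is a set of connected polylines starting at
the AIS. Each electrode within one pitch of the path (configurable) records
the waveform of its nearest path point — a deliberate idealization: the
package measures amplitudes, it does not model volume conduction.

**Waveform.** The AP shape is a negative-first biphasic transient: one sine
period under a Hann window (`synth_waveform()`). It is exactly zero-mean,
with its negative peak at one third of its 2 ms default duration. Peak
amplitudes are drawn per electrode, uniform on 3–10 sigma by default, with
the AIS electrode at 10x the median axonal amplitude. Insertions are
evaluated on the continuous time axis, so arrival times hold sub-sample
precision. Note one consequence used nowhere but worth knowing: a template
estimated by spike-triggered averaging inherits the (fractional-sample)
phase of the training arrivals, so detection-based arrival times carry a
constant sub-half-sample offset per electrode group. Per-trial differences
and variances are unaffected; distance regressions see it only as a small
zero-mean perturbation across electrodes.

**Timing.** An AP leaves the AIS and arrives at axial (arc-length) distance
$d$ after $d/v$ plus accumulated timing noise. The noise is a white
Gaussian process along the path: independent increments between consecutive
path positions with variance $r^2\,\Delta d$, where the jitter rate $r$ is
expressed as the standard deviation (us) after exactly 1 mm; the arrival
variance therefore grows linearly through the origin,
$\mathrm{Var}(d) = r^2 d$. Defaults are $v = 0.7$ m/s and $r = 100$ us at
1 mm. Electrodes at the same path position share the same noise value, and
child branches inherit the walk at their attachment point.

A strict no-overtaking guarantee (arrivals increase monotonically along a
branch within a trial) is mathematically incompatible with unbounded
Gaussian increments. The generator resolves this by redrawing any increment
that would produce a reversal. At the spacings used for kinetics recovery
(~120 um or more) reversals are essentially impossible and the marginal law
is Gaussian to high accuracy; at one-pitch spacing the conditioning is a
few percent per step and slightly shifts means and variances. The kinetics
recovery conditions below therefore use spaced electrodes, mirroring the
experimental practice of selecting well-separated high-SNR electrodes
along a branch.

**Noise.** Gaussian, per-channel standard deviation `sigma` (1 uV default,
so sigma multiples and uV coincide), optionally with an AR(1) correlation
across channel order so neighbouring channels correlate at exactly the
requested value. `sigma = 0` gives the noise-free limit. There is no 1/f
component, no shared-mode artifacts, and no stimulation-artifact waveform.

**Stimulation.** `stimulation_model()` encodes three excitability regimes:
below `v_inter` (20 mV default) the neuron never responds; at or above
`v_thr` (50 mV default, the experimentally typical threshold) it responds
in 100% of trials; in between the response probability ramps linearly with
one voltage-step of headroom so it is strictly between 0 and 1 on the
intermediate regime. Activation latency and activation jitter decay
exponentially in the normalized voltage
$V_\mathrm{norm} = (V - V_\mathrm{inter})/(V_\mathrm{thr} - V_\mathrm{inter})$.
The decay constants are anchored to three observable drops: ~130 us of
latency across the intermediate regime, a further ~40 us between
$V_\mathrm{norm} = 1$ and 3, and ~12 us of jitter between
$V_\mathrm{norm} = 1$ and 2, over floors of 100 us latency and 20 us
jitter. The exponential form itself is this package's modelling choice —
the anchors constrain only the drops, not the shape.

**Trains.** `train_model()` drives 100 episodes of 100 pulses at 100 Hz;
pulse $k$ of every episode propagates with `velocity_by_pulse[k]` and
accumulates jitter at `jitter_by_pulse[k]`. Defaults interpolate linearly
through velocities 0.71, 0.65, 0.62, 0.57 m/s and jitter rates 111, 115,
121, 124 us/mm at pulses 1, 25, 50, 100 — activity-dependent conduction
slowing of ~20% and a jitter increase of ~12% across the train. Every
pulse elicits exactly one AP: conduction is failure-free by construction.

## Detection

**Templates.** Large AIS spikes are found by a simple threshold at
5 sigma (`detect_ais_spikes()`), aligned to the negative peak within
0.5 ms of the crossing (peak alignment jitters less than crossing-time
alignment; the latter remains available), with a 2 ms dead time.
`spike_triggered_average()` averages 40 trials by default in a 10 ms
window placed 3 ms before / 7 ms after the trigger — axonal arrivals trail
the AIS, so the window favours post-trigger context. Footprints recorded
in separate electrode configurations are merged by
`assemble_footprint()`: aligned on the shared electrode's peak latency and
averaged weighted by trial counts (the weighting is this package's choice;
any merge rule consistent with alignment would do).

**Matched filter.** For a group of 1–6 neighbouring electrodes (3 and 6
are the standard sizes; groups seed on every electrode whose template
exceeds 2 sigma), the templates are stacked into one spatio-temporal
vector $s$ and the filter solves $C\,w = s$ against the spatio-temporal
noise covariance $C$ (all electrode pairs, lags up to $L-1$), estimated
from spike-free data and diagonally loaded by $10^{-3}\bar\sigma^2$. This
is the classical optimal linear detector for a known transient in Gaussian
noise; with white noise it degrades gracefully to plain template
correlation. A spatial-only whitening mode (lag-0 covariance) is available
for speed. The filter length $L$ truncates the template to its support
above $0.5\sigma$, clamped to 1–3 ms.

**Threshold.** The filter output under "noise only" and "template present"
is Gaussian with equal variance $s^\top C^{-1} s$ and means $0$ and
$E = s^\top C^{-1} s$. The Bayes rule for equal priors puts the threshold
at the midpoint $E/2$; `optimal_threshold()` adds
$(\mathrm{Var}/E)\log(\text{prior ratio})$ when noise is a priori more
likely. No manual tuning enters anywhere.

**Events and timing.** `detect_events()` takes one event per
supra-threshold excursion (its local maximum), merging events within 1 ms.
`refine_time()` interpolates the output around the peak with a
Hann-windowed sinc kernel on a 10x grid (20 kHz to an effective 200 kHz),
i.e. band-limited (Whittaker–Shannon) interpolation with a taper to
control truncation ringing; `sinc_interp()` exposes the exact periodic
(FFT zero-padding) form, which reproduces band-limited periodic signals to
machine precision. Output time axes are aligned so an event reports the
arrival at the group's *seed* electrode — important when group members sit
at different axial positions.

**Scoring.** The evaluation protocol mixes 40 AP trials with 20 noise
trials (2:1). A detection matches ground truth within 1 ms; true positives
are counted over spike trials and false positives as unmatched detections
over all detections. Both tolerances are this package's documented
choices; the protocol's trial counts are the standard ones.

## Kinetics

`classify_regimes()` applies the printed definitions verbatim:
`v_inter` = lowest voltage with any response, `v_thr` = lowest voltage
with 100% response; non-monotone response profiles are kept but flagged.
`normalize_voltage()` is the exact affine map above.

`decompose_latency_jitter()` uses the additive model
$T_\mathrm{arrival} = T_\mathrm{propagation} + T_\mathrm{activation}$ with
activation taken as immediate at the largest applied voltage, so
$T_\mathrm{propagation}$ is the mean arrival there and per-voltage
activation latency is the mean arrival minus it. For variability,
$J_\mathrm{arrival} = \mathrm{sd}(T_\mathrm{arrival})$ and the propagation
reference is the *minimum* arrival sd over voltages (the natural reading
of "lowest measured jitter ... at high voltages"; taking the value at the
single largest voltage instead changes results only by sampling noise).
The default subtracts standard deviations literally,
$J_\mathrm{activation} = J_\mathrm{arrival} - J_\mathrm{propagation}$;
because independent noise sources add in variance, a quadrature
alternative $\sqrt{J_\mathrm{arrival}^2 - J_\mathrm{propagation}^2}$ is
provided behind `jitter_domain = "variance"`. The literal form remains the
default deliberately: it is the published convention for these statistics.

`axial_distance()` projects electrodes onto the branch polyline (1-pitch
cutoff) and measures cumulative arc length — path distance with all its
turns, not the chord. `velocity_fit()` regresses per-electrode mean
arrival on axial distance (OLS; velocity = 1/slope, SE by the delta
method). `jitter_fit()` regresses per-electrode arrival *variance*
(unbiased estimator) on axial distance with a forced zero intercept — the
white-noise accumulation model makes the intercept zero at the alignment
site by construction — and reports $\sqrt{\text{slope}}$ as us at 1 mm.
Optional weighting by the chi-square variance of variance estimates
($2\sigma^4/(n-1)$) is available but off by default. Arrival tables are
referenced per trial to a proximal alignment electrode, which cancels
activation latency and jitter and any noise accumulated upstream of the
site. `train_analysis()` repeats both fits per pulse index.

## Numerical and design choices

- Sampling rate 20 kHz; trials are 10 ms (200-sample) windows; AP leaves
  the AIS 3 ms into a trial.
- Ridge loading $10^{-3}\bar\sigma^2$; Cholesky solves; block-Toeplitz
  covariance assembled from lagged cross-covariances with lags beyond the
  estimate taken as zero.
- Dead times: 2 ms for AIS triggering, 1 ms for events (stimulation spaces
  spikes at least 10 ms apart, so neither binds in the standard designs).
- Ties in AIS localization break by earliest peak latency, then lowest
  electrode id; nearest-neighbour groups break distance ties by id.
- One master seed per entry point; all randomness flows through sub-seeds
  derived from it, so any subset of the pipeline is reproducible and the
  caller's RNG state is never disturbed.
- Degenerate inputs fail loudly: zero-variance noise, singular covariance
  after loading, non-positive velocity slopes, missing threshold voltage.

## Problem sizes used by the tests and benchmark

The bundled benchmark (`detection_benchmark()`, `run_benchmark()`,
`scripts/acceptance.R`) simulates a two-branch, ~520 um arbor on a 24x24
grid (~60 electrode groups), 40 training trials, 40 AP + 20 noise
evaluation trials, amplitudes U(3, 10) sigma, with medians over 20
replicate seeds. Kinetics recovery uses a straight 1.5 mm axon with 13
electrodes at ~120 um spacing, 100 trials, true velocity 0.71 m/s and
jitter 100 us at 1 mm; regime and latency recovery use 60 trials per
voltage on a 10 mV-stepped sweep. These sizes are the package's chosen
desk-scale study conditions.

```{r, eval = FALSE}
library(axontrack)
b <- detection_benchmark(seed = 1, k = 3)
b$tp_percent; b$fp_percent

geom <- arbor_preset("recovery", seed = 21)
sim <- simulate_propagation_trials(geom$layout, n_trials = 100, seed = 21)
arr <- pipeline_arrivals(sim, k = 3, noise_seed = 22)
velocity_fit(arr, geom$layout)
jitter_fit(arr, geom$layout)
```

## What passing tests do and do not show

The generator reproduces the statistical structure the method assumes:
stereotyped waveforms, Gaussian (optionally spatially correlated) noise,
linear-in-distance jitter variance, voltage-dependent excitability,
per-pulse conduction slowing. Real recordings violate several of these in
ways the suite cannot probe: non-Gaussian and non-stationary noise,
waveform variability within a neuron, overlapping spikes from other
neurons (spike sorting is out of scope), stimulation artifacts, electrode
drift, and amplitude structure from actual volume conduction. Detection
performance near 100% on the benchmark therefore validates the
implementation, not the field performance of the method; the published
experimental figures (>90% detection, <5% false positives) are the
reference points the synthetic protocol is built around, not quantities
this package can re-measure from data.
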