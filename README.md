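# axontrack

Detection and microsecond-scale timing of *single* axonal action potentials
(APs) in high-density microelectrode array (HD-MEA) recordings, plus the
conduction statistics built on top of them.

Extracellular spikes of unmyelinated cortical axons are 1–20 noise standard
deviations — far too small for single-trial threshold detection, and
averaging destroys the trial-to-trial timing one wants to study. The
package implements the template-matching approach to this problem:

- **Electrical footprints** — spike-triggered averaging triggered on the
  large axon-initial-segment (AIS) signal yields per-electrode templates;
  the AIS is localized as the largest-amplitude, first-emerging waveform
  (`detect_ais_spikes()`, `spike_triggered_average()`, `locate_ais()`).
- **Whitened multi-electrode matched filters** — for local groups of 1–6
  electrodes, the stacked spatio-temporal template `s` and noise covariance
  `C` give the optimal linear detector `w = C⁻¹s`, with the analytic Bayes
  threshold `E/2` (`E = sᵀC⁻¹s`) requiring no manual tuning
  (`build_matched_filter()`, `optimal_threshold()`, `convolve_and_sum()`).
- **Sub-sample timing** — event peaks are refined by Whittaker–Shannon
  (windowed-sinc) interpolation on a 10× grid, 20 kHz → effective 200 kHz
  (`refine_time()`, `sinc_interp()`).
- **Conduction statistics** — excitability regimes and normalized voltage
  `Vnorm = (V − V_inter)/(V_thr − V_inter)`; decomposition
  `T_arrival = T_propagation + T_activation`,
  `J_arrival = J_activation + J_propagation`; velocity from the slope of
  arrival time vs axial (arc-length) distance; propagation jitter from the
  zero-intercept regression of arrival-time *variance* on axial distance,
  `J = √slope` in µs at 1 mm; per-pulse-index analysis of 100 Hz trains
  (`classify_regimes()`, `decompose_latency_jitter()`, `velocity_fit()`,
  `jitter_fit()`, `train_analysis()`).
- **A seeded synthetic HD-MEA generator** with full ground truth — biphasic
  waveforms propagating along a branching arbor at ~0.7 m/s, AIS amplitude
  10× the axonal median, timing noise accumulating as a white Gaussian
  process (variance linear in axial distance, 100 µs at 1 mm), voltage-
  dependent activation, and activity-dependent slowing over 100-pulse
  100 Hz trains (`arbor_model()`, `simulate_propagation_trials()`,
  `simulate_stimulation_series()`, `simulate_train()`).

The intended users are electrophysiologists and methods developers working
with dense extracellular recordings who need single-trial axonal timing
rather than averaged footprints.

## Worked example

Simulate a 1.5 mm axon (true velocity 0.71 m/s, jitter 100 µs at 1 mm),
run the full detection pipeline, and recover the conduction parameters:

```r
library(axontrack)

geom <- arbor_preset("recovery", seed = 21)   # 13 electrodes over 1.5 mm
sim  <- simulate_propagation_trials(geom$layout, n_trials = 100, seed = 21)
arr  <- pipeline_arrivals(sim, k = 3, noise_seed = 22)

velocity_fit(arr, geom$layout)
#> <propagation_fit> velocity 0.709 +/- 0.007 m/s (13 electrodes)
jitter_fit(arr, geom$layout)
#> <propagation_fit> jitter rate 102 us at 1 mm (13 electrodes)
```

The fitted velocity (0.709 m/s) and jitter rate (102 µs at 1 mm) recover
the generator's ground truth (0.71, 100) within sampling error — the
velocity from the reciprocal slope of mean arrival time vs axial distance,
the jitter rate from the square root of the through-origin variance slope.

Detection performance under the mixed-trial protocol (40 AP + 20 noise
trials per 3-electrode group, analytic thresholds):

```r
b <- detection_benchmark(seed = 1, k = 3)
c(tp = b$tp_percent, fp = b$fp_percent, groups = b$n_groups)
#>     tp     fp groups
#>    100      0     60
```

Every simulated AP is recovered with no false detections at these
signal-to-noise ratios (3–10 σ per electrode), consistent with the >90%
detection and <5% false-positive performance reported for this class of
method.

A thin command-line front end is installed at `exec/axontrack`:

```sh
axontrack simulate --preset propagation --seed 7 --out rec/
axontrack footprint --in rec/ --out fp/
axontrack detect   --in rec/ --out events.csv --k 3
axontrack benchmark --seed 1 --out metrics.json
```

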