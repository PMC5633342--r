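# Shared in-code fixtures for the test suite. Everything is generated at
# test time from fixed seeds; no data files.

# A wide-pitch straight "axon" whose electrodes project to exactly 0, 0.5
# and 1.0 mm of axial distance — convenient for closed-form checks.
straight_layout <- function(jitter_rate = 100, velocity = 0.7, seed = 1) {
  arr <- build_array(1, 3, 500)
  arb <- arbor_model(c(0, 0), list(rbind(c(0, 0), c(1000, 0))),
                     velocity = velocity, jitter_rate = jitter_rate)
  place_arbor(arb, arr, pickup_radius = 500, seed = seed)
}

# A noise-free footprint built from one clean trial of the detection-preset
# arbor (sigma = 0, jitter optionally disabled so templates are exact).
noiseless_footprint <- function(seed = 1, jitter_rate = NULL) {
  geom <- arbor_preset("detection", seed = seed, jitter_rate = jitter_rate)
  sim <- simulate_propagation_trials(geom$layout, n_trials = 1, sigma = 0,
                                     seed = seed)
  trig <- detect_ais_spikes(sim$recording, attr(geom$layout, "ais_electrode"),
                            noise_sigma = 1)
  list(fp = spike_triggered_average(sim$recording, trig), geom = geom,
       sim = sim)
}

# Standard white-noise model over the given recording electrodes.
white_noise_model <- function(layout, electrodes, sigma = 1, max_lag = 59,
                              n = 10000, seed = 99) {
  nr <- recording(synth_noise(nrow(layout), n, sigma, 0, seed), 20000,
                  layout[, c("electrode", "x", "y")])
  estimate_noise(nr, electrodes = electrodes, max_lag = max_lag)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
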