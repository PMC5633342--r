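test_that("excitability regimes follow the printed definitions", {
  prof <- classify_regimes(c(10, 20, 30, 40, 50, 60),
                           c(0, 0, 0.4, 0.9, 1.0, 1.0))
  expect_equal(attr(prof, "v_inter"), 30)
  expect_equal(attr(prof, "v_thr"), 50)
  expect_equal(prof$regime, c("sub", "sub", "intermediate", "intermediate",
                              "supra", "supra"))
  # degenerate: everything fires
  p2 <- classify_regimes(c(10, 20, 30), c(1, 1, 1))
  expect_equal(attr(p2, "v_inter"), 10)
  expect_equal(attr(p2, "v_thr"), 10)
  expect_true(all(p2$regime == "supra"))
  expect_error(classify_regimes(c(10, 20), c(0.2, 0.8)), "100%")
  expect_warning(classify_regimes(c(10, 20, 30), c(0.5, 0.2, 1)),
                 "not monotone")
})

test_that("sweep simulations recover the stimulation threshold", {
  sm <- stimulation_model(v_inter = 20, v_thr = 50)
  geom <- arbor_preset("stimulation", seed = 1)
  hits <- vapply(1:100, function(s) {
    sim <- simulate_stimulation_series(sm, geom$layout,
                                       voltages = seq(10, 100, by = 10),
                                       n_per_voltage = 60, seed = s,
                                       traces = FALSE)
    per_trial <- unique(sim$truth[, c("trial", "voltage_mV", "spike_present")])
    frac <- tapply(per_trial$spike_present, per_trial$voltage_mV, mean)
    prof <- suppressWarnings(
      classify_regimes(as.numeric(names(frac)), as.vector(frac)))
    abs(attr(prof, "v_thr") - 50) <= 10
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("voltage normalization maps the intermediate regime to [0, 1]", {
  expect_equal(normalize_voltage(50, 30, 50), 1)
  expect_equal(normalize_voltage(30, 30, 50), 0)
  expect_equal(normalize_voltage(90, 30, 50), 3)
  # affine invariance under a common voltage shift
  expect_equal(normalize_voltage(90 + 17, 30 + 17, 50 + 17), 3)
  expect_error(normalize_voltage(10, 30, 30), "undefined")
  prof <- classify_regimes(c(10, 30, 50), c(0, 0.5, 1))
  expect_equal(normalize_voltage(50, prof), 1)
})

test_that("latency/jitter decomposition follows the subtraction rules", {
  # two-voltage arithmetic: 1.63 ms at threshold vs 1.50 ms at max
  arr <- data.frame(
    voltage_mV = rep(c(50, 300), each = 20),
    trial = 1:40,
    t_s = c(rep(1.63e-3, 20), rep(1.50e-3, 20)) +
      rep(c(-1, 1), 20) * 1e-6  # +/- 1 us spread so sd is finite
  )
  dec <- decompose_latency_jitter(arr)
  expect_equal(attr(dec, "t_propagation_us"), 1500, tolerance = 1e-6)
  expect_equal(dec$t_activation_us[dec$voltage_mV == 50], 130,
               tolerance = 1e-6)
  expect_equal(dec$t_activation_us[dec$voltage_mV == 300], 0,
               tolerance = 1e-9)
  # jitter: J_prop is the minimum arrival sd; literal std subtraction
  arr2 <- data.frame(
    voltage_mV = rep(c(40, 50, 60), each = 200),
    trial = 1:600,
    t_s = 1.5e-3 + c(rnorm(200, 0, 60e-6), rnorm(200, 0, 55e-6),
                     rnorm(200, 0, 50e-6))
  )
  dec2 <- decompose_latency_jitter(arr2)
  expect_equal(attr(dec2, "j_propagation_us"), min(dec2$j_arrival_us))
  expect_equal(dec2$j_activation_us,
               dec2$j_arrival_us - attr(dec2, "j_propagation_us"))
  expect_true(all(dec2$j_activation_us >= 0))
  # variance-domain alternative
  dec2v <- decompose_latency_jitter(arr2, jitter_domain = "variance")
  expect_equal(dec2v$j_activation_us,
               sqrt(pmax(0, dec2v$j_arrival_us^2 -
                              attr(dec2v, "j_propagation_us")^2)))
})

test_that("simulated sweeps recover the activation-latency curve", {
  sm <- stimulation_model(v_inter = 20, v_thr = 50)
  geom <- arbor_preset("stimulation", seed = 1)
  el <- geom$layout$electrode[3]
  d_el <- geom$layout$d_mm[3]
  volts <- seq(30, 300, by = 30)
  checks <- unlist(lapply(1:20, function(s) {
    sim <- simulate_stimulation_series(sm, geom$layout, voltages = volts,
                                       n_per_voltage = 60, seed = 100 + s,
                                       traces = FALSE)
    arr <- arrival_table(sim)
    dec <- decompose_latency_jitter(arr, electrode = el, min_trials = 5)
    vmax <- max(dec$voltage_mV)
    truth_act <- sm$latency(dec$voltage_mV) - sm$latency(vmax)
    se <- sqrt((sm$jitter(dec$voltage_mV)^2 + 100^2 * d_el +
                  (sm$jitter(vmax)^2 + 100^2 * d_el)) / dec$n)
    abs(dec$t_activation_us - truth_act) <= 2 * se | dec$voltage_mV == vmax
  }))
  expect_gte(mean(checks), 0.9)  # ~95% nominal coverage per voltage
})

test_that("axial distance is arc length along the branch", {
  el <- data.frame(electrode = 1:2, x = c(0, 1000), y = c(0, 0))
  bp <- axial_distance(rbind(c(0, 0), c(1000, 0)), el)
  expect_equal(bp$d_mm, c(0, 1))
  # right-angle path: arc length 1 mm, chord ~0.707 mm
  el2 <- data.frame(electrode = 1:2, x = c(0, 500), y = c(0, 500))
  bp2 <- axial_distance(rbind(c(0, 0), c(500, 0), c(500, 500)), el2)
  expect_equal(bp2$d_mm[2], 1)
  expect_equal(sqrt(sum((el2[2, 2:3] - el2[1, 2:3])^2)) / 1000, 0.707,
               tolerance = 1e-3)
  # far electrodes are excluded
  el3 <- data.frame(electrode = 1:3, x = c(0, 500, 500), y = c(0, 200, 10))
  expect_message(bp3 <- axial_distance(rbind(c(0, 0), c(1000, 0)), el3),
                 "excluded")
  expect_setequal(bp3$electrode, c(1, 3))
  # simulated arbor: layout distances match projection-based distances
  geom <- arbor_preset("recovery", seed = 3)
  bp4 <- axial_distance(geom$arbor$branches[[1]],
                        geom$layout[, c("electrode", "x", "y")])
  expect_equal(bp4$d_mm[match(geom$layout$electrode, bp4$electrode)],
               geom$layout$d_mm, tolerance = 17.8 / 1000)
})

test_that("velocity regression inverts the fitted slope", {
  arr <- data.frame(electrode = rep(1:2, each = 5), trial = rep(1:5, 2),
                    t_s = rep(c(0, 1.4286e-3), each = 5))
  path <- data.frame(electrode = 1:3, d_mm = c(0, 1, 2))
  arr3 <- rbind(arr, data.frame(electrode = 3, trial = 1:5,
                                t_s = 2 * 1.4286e-3))
  vf <- suppressWarnings(velocity_fit(arr3, path))  # exact fit: zero residual
  expect_equal(vf$velocity_mps, 0.7, tolerance = 1e-4)
  # constant times: error
  flat <- data.frame(electrode = rep(1:3, each = 3), trial = rep(1:3, 3),
                     t_s = 1e-3)
  expect_error(velocity_fit(flat, path), "slope")
  # permutation invariance
  perm <- arr3[sample(nrow(arr3)), ]
  expect_equal(suppressWarnings(velocity_fit(perm, path))$velocity_mps,
               vf$velocity_mps)
})

test_that("jitter regression through the origin yields the rate exactly", {
  # variances 0.01/0.02/0.03 ms^2 at 1/2/3 mm -> 100 us at 1 mm
  set.seed(1)
  mk <- function(d_mm, var_ms2, n = 2001) {
    z <- qnorm(seq(0.0005, 0.9995, length.out = n))
    z <- z / sd(z) * sqrt(var_ms2) * 1e-3  # exact sample sd, seconds
    data.frame(electrode = d_mm * 10, trial = seq_len(n), t_s = z)
  }
  arr <- rbind(mk(1, 0.01), mk(2, 0.02), mk(3, 0.03))
  path <- data.frame(electrode = c(10, 20, 30), d_mm = 1:3)
  jf <- jitter_fit(arr, path)
  expect_equal(jf$jitter_rate_us_mm, 100, tolerance = 1e-9)
  expect_equal(jf$variance_slope_us2_mm, 1e4, tolerance = 1e-6)
  # zero-jitter simulation
  lay <- straight_layout(jitter_rate = 0)
  sim <- simulate_propagation_trials(lay, n_trials = 30, sigma = 1, seed = 5,
                                     traces = FALSE)
  arr0 <- arrival_table(sim, align_electrode = lay$electrode[1])
  jf0 <- jitter_fit(arr0, lay)
  expect_equal(jf0$jitter_rate_us_mm, 0, tolerance = 1e-9)
  # (a negative through-origin slope cannot arise from non-negative
  # variances at positive distances; that error branch is purely defensive)
})

test_that("velocity and jitter recover the simulated truth", {
  geom <- arbor_preset("recovery", seed = 2)  # v = 0.71, 100 us at 1 mm
  sim <- simulate_propagation_trials(geom$layout, n_trials = 100, sigma = 1,
                                     seed = 12, traces = FALSE)
  arr <- arrival_table(sim, align_electrode = geom$layout$electrode[1])
  vf <- velocity_fit(arr, geom$layout)
  expect_rel_equal(vf$velocity_mps, 0.71, 0.02)
  hits <- vapply(1:50, function(s) {
    si <- simulate_propagation_trials(geom$layout, n_trials = 100, sigma = 1,
                                      seed = 200 + s, traces = FALSE)
    a <- arrival_table(si, align_electrode = geom$layout$electrode[1])
    abs(jitter_fit(a, geom$layout)$jitter_rate_us_mm - 100) / 100 <= 0.15
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("a common per-trial offset cancels under alignment", {
  geom <- arbor_preset("recovery", seed = 4)
  sim <- simulate_propagation_trials(geom$layout, n_trials = 50, sigma = 1,
                                     seed = 8, traces = FALSE)
  arr <- arrival_table(sim, align_electrode = geom$layout$electrode[1])
  shifted <- sim$truth
  offs <- rnorm(50, 0, 5e-4)
  shifted$true_time_s <- shifted$true_time_s + offs[shifted$trial]
  arr2 <- arrival_table(shifted, align_electrode = geom$layout$electrode[1])
  ord <- order(arr$trial, arr$electrode)
  ord2 <- order(arr2$trial, arr2$electrode)
  expect_equal(arr2$t_s[ord2], arr$t_s[ord], tolerance = 1e-12)
  expect_equal(velocity_fit(arr2, geom$layout)$velocity_mps,
               velocity_fit(arr, geom$layout)$velocity_mps)
})

test_that("train analysis resolves per-pulse slowing and a null model", {
  lay <- straight_layout()
  tm0 <- train_model(n_episodes = 40, n_pulses = 20,
                     velocity_anchors = rep(0.7, 4),
                     jitter_anchors = rep(100, 4))
  sim0 <- simulate_train(tm0, lay, seed = 31)
  arr0 <- arrival_table(sim0, align_electrode = lay$electrode[1])
  ta0 <- train_analysis(arr0, lay, pulse_indices = c(1, 10, 20))
  expect_lt(diff(range(ta0$velocity_mps)) / mean(ta0$velocity_mps), 0.03)
  # default anchors on the recovery arbor
  geom <- arbor_preset("recovery", seed = 6)
  tm <- train_model(n_episodes = 100, n_pulses = 100)
  sim <- simulate_train(tm, geom$layout, seed = 32)
  arr <- arrival_table(sim, align_electrode = geom$layout$electrode[1])
  ta <- train_analysis(arr, geom$layout)
  expect_lt(ta$velocity_mps[4], ta$velocity_mps[1])
  expect_gt(attr(ta, "velocity_change_pct"), 15)
  expect_lt(attr(ta, "velocity_change_pct"), 25)
})
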