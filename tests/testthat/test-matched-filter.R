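test_that("noise estimation recovers sigma and the correlation structure", {
  lay <- straight_layout()
  el <- lay[, c("electrode", "x", "y")]
  rec <- recording(synth_noise(3, 200000, 1, 0, seed = 17), 20000, el)
  nm <- estimate_noise(rec, max_lag = 3)
  expect_true(all(abs(nm$sigma - 1) < 0.01))
  off <- nm$ccov[, , 1][upper.tri(matrix(0, 3, 3))]
  expect_true(all(abs(off) < 0.02))
  # lagged autocovariance of white noise is ~0
  expect_true(all(abs(nm$ccov[, , 2:4]) < 0.02))
  # correlated noise: lag-0 neighbour cross-covariance = 0.5
  recc <- recording(synth_noise(3, 200000, 1, 0.5, seed = 18), 20000, el)
  nmc <- estimate_noise(recc, max_lag = 0)
  expect_equal(nmc$ccov[1, 2, 1], 0.5, tolerance = 0.02)
  expect_equal(nmc$ccov[2, 3, 1], 0.5, tolerance = 0.02)
  # degenerate input
  expect_error(estimate_noise(recording(matrix(0, 3, 5000), 20000, el)),
               "zero variance")
  # insufficient spike-free data
  expect_error(estimate_noise(rec, max_lag = 59,
                              spike_free_mask = c(rep(TRUE, 100),
                                                  rep(FALSE, 199900))),
               "insufficient")
  # masking honours run boundaries: a masked-out spike leaves stats intact
  x <- synth_noise(3, 50000, 1, 0, seed = 19)
  x[, 25000:25040] <- x[, 25000:25040] + 50
  mrec <- recording(x, 20000, el)
  mask <- rep(TRUE, 50000); mask[24950:25090] <- FALSE
  nm2 <- estimate_noise(mrec, max_lag = 2, spike_free_mask = mask)
  expect_true(all(abs(nm2$sigma - 1) < 0.02))
})

test_that("electrode grouping nests across k and respects the seed floor", {
  nf <- noiseless_footprint(seed = 2)
  g1 <- group_electrodes(nf$fp, nf$geom$array, k = 1)
  expect_true(all(lengths(g1) == 1))
  g3 <- group_electrodes(nf$fp, nf$geom$array, k = 3)
  g6 <- group_electrodes(nf$fp, nf$geom$array, k = 6)
  expect_identical(names(g3), names(g6))
  for (nm in names(g3)) {
    expect_true(all(g3[[nm]] %in% g6[[nm]]))  # nearest-neighbour nesting
    expect_equal(g3[[nm]][1], as.integer(nm))  # seed first
    xy <- axontrack:::electrode_xy(nf$geom$array, g3[[nm]])
    d <- sqrt((xy[, 1] - xy[1, 1])^2 + (xy[, 2] - xy[1, 2])^2)
    expect_lte(max(d), 2 * 17.8)  # k = 3 groups span at most 2 pitches
  }
  # the amplitude floor removes sub-2-sigma seeds
  ghigh <- group_electrodes(nf$fp, nf$geom$array, k = 3, floor_amp = 50)
  expect_lt(length(ghigh), length(g3))
})

test_that("the matched filter reduces to scaled correlation in white noise", {
  nf <- noiseless_footprint(seed = 4, jitter_rate = 0)
  lay <- nf$geom$layout
  g <- group_electrodes(nf$fp, k = 1)[[5]]
  nm <- white_noise_model(lay, g, sigma = 1, n = 60000)
  filt <- build_matched_filter(nf$fp, g, nm)
  rows <- match(g, nf$fp$peaks$electrode)
  # locate the template segment used by the filter
  L <- ncol(filt$coefficients)
  i0 <- round((filt$t_start_s + nf$fp$pre_s) * nf$fp$fs) + 1
  S <- nf$fp$waveforms[rows, i0:(i0 + L - 1), drop = FALSE]
  expect_equal(filt$template, S)
  # coefficients = template / sigma^2 (up to estimation error and ridge)
  expect_equal(as.vector(filt$coefficients), as.vector(S),
               tolerance = 0.1)
  expect_rel_equal(filt$expected_peak, sum(S^2), 0.1)
  # analytic threshold: midpoint at equal priors, larger when noise likelier
  expect_equal(filt$threshold, filt$expected_peak / 2)
  expect_gt(optimal_threshold(filt, prior_ratio = 3), filt$threshold)
  expect_lt(optimal_threshold(filt, prior_ratio = 1 / 3), filt$threshold)
})

test_that("whitened filters beat plain correlation in correlated noise", {
  nf <- noiseless_footprint(seed = 6, jitter_rate = 0)
  lay <- nf$geom$layout
  g <- group_electrodes(nf$fp, nf$geom$array, k = 3)[[10]]
  gi <- match(g, lay$electrode)
  corr_rec <- recording(synth_noise(nrow(lay), 60000, 1, 0.6, seed = 61),
                        20000, lay[, c("electrode", "x", "y")])
  nm <- estimate_noise(corr_rec, electrodes = g, max_lag = 59)
  f_white <- build_matched_filter(nf$fp, g, nm)
  # plain correlation filter: identity-covariance noise model
  nm_id <- nm
  for (l in seq_len(dim(nm_id$ccov)[3]))
    nm_id$ccov[, , l] <- diag(mean(nm$sigma^2), 3) * (l == 1)
  f_plain <- build_matched_filter(nf$fp, g, nm_id)
  # Monte-Carlo output SNR over 200 noise trials with one inserted template
  snr <- function(filt) {
    peaks <- nulls <- numeric(200)
    for (i in 1:200) {
      X <- synth_noise(nrow(lay), 400, 1, 0.6, seed = 1000 + i)[gi, ]
      nulls[i] <- convolve_and_sum(X, filt)[200]
      L <- ncol(filt$template)
      X[, 150:(150 + L - 1)] <- X[, 150:(150 + L - 1)] + filt$template
      y <- convolve_and_sum(X, filt)
      peaks[i] <- y[150 + filt$peak_offset]
    }
    mean(peaks) / sd(nulls)
  }
  expect_gt(snr(f_white), snr(f_plain))
})

test_that("filter output matches the brute-force sliding dot product", {
  nf <- noiseless_footprint(seed = 5)
  for (case in 1:5) {
    k <- sample(c(1, 3, 6), 1)
    g <- sample(group_electrodes(nf$fp, nf$geom$array, k = k), 1)[[1]]
    nm <- white_noise_model(nf$geom$layout, g, n = 5000, seed = 40 + case)
    filt <- build_matched_filter(nf$fp, g, nm)
    L <- ncol(filt$coefficients)
    n <- 300
    X <- synth_noise(length(g), n, 1, 0, seed = 50 + case)
    y <- convolve_and_sum(X, filt)
    # O(N L) oracle
    oracle <- numeric(n)
    for (u in 1:(n - L + 1)) {
      s <- 0
      for (e in seq_along(g)) s <- s + sum(X[e, u:(u + L - 1)] *
                                             filt$coefficients[e, ])
      oracle[u + filt$peak_offset] <- s
    }
    expect_lt(max(abs(y - oracle)), 1e-9 * filt$expected_peak)
  }
})

test_that("a clean template yields expected_peak and noise propagates as predicted", {
  nf <- noiseless_footprint(seed = 8, jitter_rate = 0)
  lay <- nf$geom$layout
  g <- group_electrodes(nf$fp, nf$geom$array, k = 3)[[15]]
  nm <- white_noise_model(lay, g, n = 100000, seed = 81)
  filt <- build_matched_filter(nf$fp, g, nm)
  L <- ncol(filt$template)
  X <- matrix(0, 3, 600)
  X[, 300:(300 + L - 1)] <- filt$template
  y <- convolve_and_sum(X, filt)
  expect_equal(which.max(y), 300 + filt$peak_offset)
  expect_rel_equal(max(y), filt$expected_peak, 1e-6)
  # pure noise through the filter: mean 0, variance = output_noise_var
  Z <- synth_noise(3, 200000, 1, 0, seed = 82)
  yz <- convolve_and_sum(Z, filt)
  v <- attr(yz, "valid")
  yz <- yz[v[1]:v[2]]
  expect_lt(abs(mean(yz)), 3 * sd(yz) / sqrt(500))  # heavily autocorrelated
  expect_rel_equal(var(yz), filt$output_noise_var, 0.05)
})

test_that("event extraction respects thresholds, peaks and dead time", {
  expect_equal(nrow(detect_events(rep(0.1, 1000), threshold = 1, fs = 20000)),
               0)
  nf <- noiseless_footprint(seed = 9, jitter_rate = 0)
  g <- group_electrodes(nf$fp, nf$geom$array, k = 3)[[8]]
  nm <- white_noise_model(nf$geom$layout, g, n = 50000, seed = 91)
  filt <- build_matched_filter(nf$fp, g, nm)
  L <- ncol(filt$template)
  X <- matrix(0, 3, 20000)
  ins <- c(500, 3000, 7000, 12000, 18000)
  for (i in ins) X[, i:(i + L - 1)] <- X[, i:(i + L - 1)] + filt$template
  y <- convolve_and_sum(X, filt)
  ev <- detect_events(y, filter = filt)
  expect_equal(nrow(ev), 5)
  expect_true(all(abs(ev$sample - (ins + filt$peak_offset)) <= 1))
  # two copies closer than the dead time merge into the larger peak
  X2 <- matrix(0, 3, 2000)
  X2[, 500:(500 + L - 1)] <- filt$template
  X2[, 512:(512 + L - 1)] <- X2[, 512:(512 + L - 1)] + 0.7 * filt$template
  ev2 <- detect_events(convolve_and_sum(X2, filt), filter = filt)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$sample, 500 + filt$peak_offset, tolerance = 2)
})

test_that("sinc interpolation reproduces a band-limited sinusoid", {
  n <- 200; f <- 7
  x <- sin(2 * pi * f * (0:(n - 1)) / n)
  y <- sinc_interp(x, 10)
  tt <- (0:(n * 10 - 1)) / (n * 10)
  expect_lt(max(abs(y - sin(2 * pi * f * tt))), 1e-6)
  expect_equal(sinc_interp(x, 1), x)
})

test_that("sub-sample refinement recovers fractional insertion times", {
  # footprint whose template peaks sit exactly on the sampling grid
  fs <- 20000
  lay <- straight_layout()
  amps <- c(6, 4, 8)
  wave <- matrix(0, 3, 200)
  for (e in 1:3)  # continuous waveform with its peak exactly at sample 60
    wave[e, ] <- axontrack:::eval_waveform((0:199) / fs, amps[e], 0.002,
                                           59 / fs)
  fpg <- axontrack:::new_footprint(lay[, c("electrode", "x", "y")], wave, fs,
                                   3e-3, rep(40, 3))
  g <- lay$electrode
  nm <- white_noise_model(lay, g, n = 50000, seed = 101)
  filt <- build_matched_filter(fpg, g, nm)
  mk_trace <- function(frac) {
    # waveforms on the continuous axis, template peaks at sample 400 + frac
    n <- 800
    X <- matrix(0, 3, n)
    t_pk <- (400 - 1 + frac) / fs
    tt <- (0:(n - 1)) / fs
    for (e in 1:3)
      X[e, ] <- axontrack:::eval_waveform(tt, amps[e], 0.002, t_pk)
    X
  }
  # on-grid insertion: refined time equals the sample time
  y0 <- convolve_and_sum(mk_trace(0), filt)
  ev0 <- detect_events(y0, filter = filt)
  t0 <- refine_time(y0, ev0$sample[1], fs)
  expect_true(attr(t0, "refined"))
  expect_equal(as.numeric(t0), (400 - 1) / fs, tolerance = 0.05 / fs)
  # 0.3-sample offset recovered within 0.1 sample (the fine-grid step)
  y3 <- convolve_and_sum(mk_trace(0.3), filt)
  ev3 <- detect_events(y3, filter = filt)
  t3 <- refine_time(y3, ev3$sample[1], fs)
  expect_lte(abs(as.numeric(t3) - (400 - 1 + 0.3) / fs), 0.1 / fs + 1e-12)
  # edge events fall back to sample resolution, flagged
  te <- refine_time(y0, 3L, fs)
  expect_false(attr(te, "refined"))
})

test_that("the analytic threshold matches a brute-force grid optimum", {
  # low-amplitude single-electrode setting on the 40:20 mixed protocol
  fs <- 20000
  lay <- straight_layout(jitter_rate = 0)
  lay$amplitude[] <- 2
  sim_tr <- simulate_propagation_trials(lay, n_trials = 60, sigma = 1,
                                        seed = 71,
                                        spike_present = rep(c(TRUE, FALSE),
                                                            c(40, 20)))
  nm <- white_noise_model(lay, lay$electrode[2], n = 50000, seed = 72)
  # clean template (training noise is not what this check is about)
  clean <- simulate_propagation_trials(lay, n_trials = 1, sigma = 0, seed = 1)
  cleanfp <- spike_triggered_average(clean$recording, 0.003)
  filt <- build_matched_filter(cleanfp, lay$electrode[2], nm,
                               support_floor = 0.3)
  y <- convolve_and_sum(sim_tr$recording, filt)
  truth <- sim_tr$truth[sim_tr$truth$electrode == lay$electrode[2],
                        c("trial", "spike_present", "true_time_s")]
  total_err <- function(thr) {
    ev <- detect_events(y, threshold = thr, fs = fs)
    ev$trial <- pmin(floor(ev$time_s / 0.010) + 1L, 60L)
    r <- evaluate_detection(ev, truth)
    miss <- r$n_spike_trials * r$fn_percent / 100
    miss + r$n_false_positives
  }
  grid <- seq(filt$expected_peak * 0.05, filt$expected_peak * 1.5,
              length.out = 101)
  errs <- vapply(grid, total_err, 0)
  expect_lte(total_err(filt$threshold), min(errs))
  # and the grid scan is not vacuous: extreme thresholds do fail
  expect_gt(errs[1], 0)
  expect_gt(errs[101], 0)
})

test_that("detection scoring implements the 2:1 mixed-trial arithmetic", {
  truth <- data.frame(trial = 1:60,
                      spike_present = rep(c(TRUE, FALSE), c(40, 20)),
                      true_time_s = c((0:39) * 0.010 + 0.004, rep(NA, 20)))
  perfect <- data.frame(trial = 1:40, time_s = (0:39) * 0.010 + 0.004)
  r <- evaluate_detection(perfect, truth)
  expect_equal(r$tp_percent, 100)
  expect_equal(r$fp_percent, 0)
  expect_equal(r$fn_percent, 0)
  # a detector firing once per trial regardless: FP = 20/60 = 33.3%
  blind <- data.frame(trial = 1:60, time_s = (0:59) * 0.010 + 0.004)
  r2 <- evaluate_detection(blind, truth)
  expect_equal(r2$fp_percent, 100 * 20 / 60, tolerance = 1e-9)
  # no detections at all: FP defined as 0
  none <- data.frame(trial = integer(0), time_s = numeric(0))
  expect_equal(evaluate_detection(none, truth)$fp_percent, 0)
  expect_equal(evaluate_detection(none, truth)$tp_percent, 0)
})
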