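#' Score detections against ground truth
#'
#' Matches detected events to ground-truth spikes per trial within
#' `tolerance_ms`. The true-positive percentage is the fraction of
#' spike-containing trials with at least one matched event; the
#' false-negative percentage is its complement; the false-positive
#' percentage is the number of unmatched detections expressed relative to
#' the total number of detections (0 when there are no detections).
#'
#' @param events Data frame with `trial` and `time_s` columns.
#' @param truth Data frame with one row per trial: `trial`,
#'   `spike_present`, `true_time_s` (NA for noise trials).
#' @param tolerance_ms Matching tolerance (default 1 ms).
#' @return List: `tp_percent`, `fn_percent`, `fp_percent`, `n_spike_trials`,
#'   `n_detections`, `n_false_positives`.
#' @export
evaluate_detection <- function(events, truth, tolerance_ms = 1) {
  tol <- tolerance_ms / 1000
  spike_trials <- truth$trial[truth$spike_present]
  matched_trial <- logical(length(spike_trials))
  fp <- 0L
  if (nrow(events)) {
    tt <- truth$true_time_s[match(events$trial, truth$trial)]
    hit <- !is.na(tt) & abs(events$time_s - tt) <= tol
    fp <- sum(!hit)
    matched_trial <- spike_trials %in% events$trial[hit]
  }
  n_det <- nrow(events)
  list(tp_percent = 100 * mean(matched_trial),
       fn_percent = 100 * (1 - mean(matched_trial)),
       fp_percent = if (n_det == 0) 0 else 100 * fp / n_det,
       n_spike_trials = length(spike_trials),
       n_detections = n_det, n_false_positives = fp)
}

#' Mixed-trial detection benchmark on synthetic recordings
#'
#' Runs the full evaluation protocol on one seeded synthetic arbor:
#' simulate 40 training trials, build the footprint by AIS-triggered
#' spike-triggered averaging, form `k`-electrode groups, estimate the noise
#' covariance from a spike-free stretch, build whitened matched filters
#' with their analytic thresholds, then detect on a fresh mix of 40 AP
#' trials and 20 noise trials (2:1) and score against ground truth at the
#' group seed electrode. Percentages are pooled over all groups.
#'
#' @param seed Master seed.
#' @param k Electrodes per group (1, 3 or 6).
#' @param n_train Training trials for the templates.
#' @param n_test,n_noise Evaluation AP and noise trials.
#' @param sigma Noise standard deviation (uV).
#' @param amplitude_range Axonal peak amplitudes (sigma multiples).
#' @param whitening Passed to [build_matched_filter()].
#' @param spatial_corr Neighbouring-channel noise correlation.
#' @param tolerance_ms Truth-matching tolerance.
#' @param noise_samples Length of the spike-free stretch used for the noise
#'   model.
#' @param preset_seed Seed for the arbor geometry/amplitude draw (defaults
#'   to `seed` so each replicate gets its own amplitude profile).
#' @return List: `tp_percent`, `fp_percent`, `n_groups`, `per_group` data
#'   frame, `k`, `seed`.
#' @export
detection_benchmark <- function(seed = 1, k = 3, n_train = 40, n_test = 40,
                                n_noise = 20, sigma = 1,
                                amplitude_range = c(3, 10),
                                whitening = "full", spatial_corr = 0,
                                tolerance_ms = 1, noise_samples = 10000,
                                preset_seed = NULL) {
  seeds <- derive_seeds(seed, 4)
  geom <- arbor_preset("detection", seed = preset_seed %||% seeds[1])
  if (!identical(amplitude_range, c(3, 10))) {
    geom$layout <- place_arbor(geom$arbor, geom$array,
                               amplitude_range = amplitude_range,
                               seed = preset_seed %||% seeds[1])
  }
  layout <- geom$layout
  ais <- attr(layout, "ais_electrode")

  # --- training: templates from AIS-triggered averages ----------------------
  train <- simulate_propagation_trials(layout, n_trials = n_train,
                                       sigma = sigma, seed = seeds[2],
                                       spatial_corr = spatial_corr)
  trig <- detect_ais_spikes(train$recording, ais, noise_sigma = sigma)
  fp <- spike_triggered_average(train$recording, trig)

  # --- noise model from a spike-free stretch --------------------------------
  noise_rec <- recording(synth_noise(nrow(layout), noise_samples, sigma,
                                     spatial_corr, seeds[3]),
                         train$recording$fs,
                         layout[, c("electrode", "x", "y")])

  # --- evaluation mix -------------------------------------------------------
  n_eval <- n_test + n_noise
  spike_present <- with_seed(seeds[4], sample(rep(c(TRUE, FALSE),
                                                  c(n_test, n_noise))))
  eval_sim <- simulate_propagation_trials(layout, n_trials = n_eval,
                                          sigma = sigma, seed = seeds[4],
                                          spike_present = spike_present,
                                          spatial_corr = spatial_corr)
  groups <- group_electrodes(fp, geom$array, k = k, noise_sigma = sigma)
  trial_s <- 0.010
  res <- lapply(groups, function(g) {
    noise <- estimate_noise(noise_rec, electrodes = g,
                            max_lag = if (whitening == "full") 59 else 0)
    filt <- build_matched_filter(fp, g, noise, whitening = whitening)
    y <- convolve_and_sum(eval_sim$recording, filt)
    ev <- detect_events(y, filter = filt)
    if (nrow(ev)) {
      ev$time_s <- vapply(ev$sample, function(s)
        as.numeric(refine_time(y, s, filt$fs)), 0)
      ev$trial <- pmin(floor(ev$time_s / trial_s) + 1L, n_eval)
    } else ev$trial <- integer(0)
    truth_g <- eval_sim$truth[eval_sim$truth$electrode == g[1],
                              c("trial", "spike_present", "true_time_s")]
    evaluate_detection(ev, truth_g, tolerance_ms = tolerance_ms)
  })
  per_group <- data.frame(
    seed_electrode = as.integer(names(groups)),
    tp_percent = vapply(res, function(r) r$tp_percent, 0),
    fp_percent = vapply(res, function(r) r$fp_percent, 0),
    n_detections = vapply(res, function(r) r$n_detections, 0L)
  )
  n_matched <- sum(vapply(res, function(r)
    r$n_spike_trials * r$tp_percent / 100, 0))
  n_spikes <- sum(vapply(res, function(r) r$n_spike_trials, 0))
  n_det <- sum(per_group$n_detections)
  n_fp <- sum(vapply(res, function(r) r$n_false_positives, 0))
  list(tp_percent = 100 * n_matched / n_spikes,
       fp_percent = if (n_det == 0) 0 else 100 * n_fp / n_det,
       n_groups = length(groups), per_group = per_group, k = k, seed = seed)
}

#' Detection-based arrival times along a simulated axon
#'
#' Runs the detection pipeline (templates, per-electrode-group matched
#' filters, sub-sample peak refinement) on a propagation simulation and
#' returns the arrival table of detected times, optionally aligned to the
#' proximal electrode — the full measurement chain feeding the kinetics
#' fits.
#'
#' @param sim A [simulate_propagation_trials()] result with traces.
#' @param k Group size for the matched filters.
#' @param sigma Noise standard deviation (uV).
#' @param align If TRUE (default), align arrivals to the first path
#'   electrode per trial.
#' @param noise_seed Seed for the spike-free noise stretch.
#' @return Arrival table (`trial`, `electrode`, `t_s`).
#' @export
pipeline_arrivals <- function(sim, k = 3, sigma = 1, align = TRUE,
                              noise_seed = 1) {
  layout <- sim$layout
  rec <- sim$recording
  ais <- attr(layout, "ais_electrode")
  trig <- detect_ais_spikes(rec, ais, noise_sigma = sigma)
  fp <- spike_triggered_average(rec, trig)
  noise_rec <- recording(synth_noise(nrow(layout), 10000, sigma, 0,
                                     noise_seed),
                         rec$fs, layout[, c("electrode", "x", "y")])
  groups <- group_electrodes(fp, k = k, noise_sigma = sigma)
  trial_s <- 0.010
  n_trials <- length(sim$trial_starts)
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    noise <- estimate_noise(noise_rec, electrodes = g, max_lag = 59)
    filt <- build_matched_filter(fp, g, noise)
    y <- convolve_and_sum(rec, filt)
    ev <- detect_events(y, filter = filt)
    if (!nrow(ev)) return(NULL)
    ev$time_s <- vapply(ev$sample, function(s)
      as.numeric(refine_time(y, s, filt$fs)), 0)
    ev$trial <- pmin(floor(ev$time_s / trial_s) + 1L, n_trials)
    # keep the strongest event per trial
    ev <- ev[order(ev$trial, -ev$score), ]
    ev <- ev[!duplicated(ev$trial), ]
    data.frame(trial = ev$trial, electrode = as.integer(nm),
               t_s = ev$time_s - sim$trial_starts[ev$trial])
  })
  tab <- do.call(rbind, rows)
  if (align) {
    first_el <- layout$electrode[which.min(layout$d_mm)]
    ref <- tab[tab$electrode == first_el, c("trial", "t_s")]
    names(ref)[2] <- ".t_ref"
    tab <- merge(tab, ref, by = "trial")
    tab$t_s <- tab$t_s - tab$.t_ref
    tab$.t_ref <- NULL
    attr(tab, "alignment_electrode") <- first_el
  }
  tab
}

#' Full synthetic benchmark: detection and kinetics recovery
#'
#' Seeded end-to-end benchmark used by the command line and the acceptance
#' machinery: (1) the mixed-trial detection protocol with 3- and
#' 6-electrode groups, medians over `n_reps` replicate seeds; (2) velocity
#' and jitter-rate recovery through the full detection pipeline on the
#' 1.5 mm recovery arbor (true velocity 0.71 m/s, jitter 100 us at 1 mm).
#'
#' @param seed Master seed.
#' @param n_reps Replicate seeds for the detection medians.
#' @param n_recovery_trials Trials for the kinetics recovery.
#' @return Named list of metrics (percentages, m/s, us at 1 mm).
#' @export
run_benchmark <- function(seed = 1, n_reps = 20, n_recovery_trials = 100) {
  seeds <- derive_seeds(seed, n_reps + 2)
  b3 <- lapply(seeds[1:n_reps], detection_benchmark, k = 3)
  b6 <- lapply(seeds[1:n_reps], detection_benchmark, k = 6)
  geom <- arbor_preset("recovery", seed = seeds[n_reps + 1])
  sim <- simulate_propagation_trials(geom$layout,
                                     n_trials = n_recovery_trials,
                                     sigma = 1, seed = seeds[n_reps + 1])
  arr <- pipeline_arrivals(sim, k = 3, sigma = 1,
                           noise_seed = seeds[n_reps + 2])
  path <- sim$layout[, c("electrode", "d_mm")]
  vf <- velocity_fit(arr, path)
  jf <- jitter_fit(arr, path)
  list(tp_percent = median(vapply(b3, function(x) x$tp_percent, 0)),
       fp_percent = median(vapply(b3, function(x) x$fp_percent, 0)),
       tp_percent_k6 = median(vapply(b6, function(x) x$tp_percent, 0)),
       fp_percent_k6 = median(vapply(b6, function(x) x$fp_percent, 0)),
       velocity_mps = vf$velocity_mps,
       jitter_rate_us_per_mm = jf$jitter_rate_us_mm,
       n_reps = n_reps, seed = seed)
}
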