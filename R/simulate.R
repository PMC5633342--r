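# ---- ground-truth arrival machinery ----------------------------------------

# Simulate per-trial arrival times (s, relative to the AP leaving the AIS)
# for every layout electrode. The timing noise is a white Gaussian process
# along the path: independent increments between consecutive path nodes with
# variance jitter_rate^2 * delta_d (rate in us at 1 mm, d in mm); electrodes
# at the same path position share the same walk value, child branches
# inherit the walk at their attachment point. `velocity` and `jitter_rate`
# may be scalars or per-trial vectors.
#
# `enforce_order` guards the no-overtaking guarantee: increments that would
# make an arrival non-increasing along the path are redrawn (truncated
# Gaussian); at the package's default geometries such redraws are rare and
# the marginal distribution stays Gaussian to good accuracy.
sim_arrivals_rel <- function(layout, n_trials, velocity = NULL,
                             jitter_rate = NULL, seed = NULL,
                             enforce_order = TRUE) {
  arbor <- attr(layout, "arbor")
  tree <- attr(layout, "tree")
  vel <- rep_len(velocity %||% arbor$velocity, n_trials)       # m/s == mm/ms
  rate <- rep_len(jitter_rate %||% arbor$jitter_rate, n_trials) # us at 1 mm
  walks <- vector("list", tree$n_branches)
  with_seed(seed, {
    for (b in seq_len(tree$n_branches)) {
      nd <- tree$d_nodes[[b]]
      nn <- length(nd)
      start <- if (b == 1) numeric(n_trials)
               else walks[[tree$parent[b]]][, tree$attach_node[b]]
      W <- matrix(0, n_trials, nn)
      W[, 1] <- start
      if (nn > 1) {
        dd <- diff(nd)  # mm
        for (j in seq_len(nn - 1)) {
          sd_j <- rate * sqrt(dd[j])
          inc <- rnorm(n_trials, 0, sd_j)
          if (enforce_order) {
            lb <- -dd[j] / vel * 1000  # us needed to keep arrivals increasing
            for (att in 1:100) {
              bad <- which(inc <= lb)
              if (!length(bad)) break
              inc[bad] <- rnorm(length(bad), 0, sd_j[bad])
            }
            inc <- pmax(inc, lb + 1e-3)
          }
          W[, j + 1] <- W[, j] + inc
        }
      }
      walks[[b]] <- W
    }
  })
  # arrival = d / v + walk, per trial and electrode (seconds)
  n_el <- nrow(layout)
  out <- matrix(0, n_trials, n_el)
  for (i in seq_len(n_el)) {
    w <- walks[[tree$el_branch[i]]][, tree$el_node[i]]
    out[, i] <- layout$d_mm[i] / vel * 1e-3 + w * 1e-6
  }
  colnames(out) <- layout$electrode
  out
}

# Noise traces with the sigma = 0 (noise-free) limit allowed.
noise_or_zero <- function(n_el, n_samp, sigma, spatial_corr, seed) {
  if (sigma == 0) matrix(0, n_el, n_samp)
  else synth_noise(n_el, n_samp, sigma, spatial_corr, seed)
}

# amplitude unit: sigma multiples, except in the noise-free limit where
# amplitudes are taken directly in uV
amp_unit <- function(sigma) if (sigma > 0) sigma else 1

# Insert analytic waveforms into a noise matrix at sub-sample arrival times.
# `arrivals` is n_trials x n_electrodes (s, absolute); amplitude per
# electrode in sigma multiples.
insert_spikes <- function(traces, fs, arrivals, spike_present, amplitudes,
                          sigma, duration_s = 0.002) {
  n_samp <- ncol(traces)
  for (tr in which(spike_present)) {
    for (e in seq_len(ncol(arrivals))) {
      t_pk <- arrivals[tr, e]
      i0 <- max(1L, ceiling((t_pk - WAVE_PEAK_FRAC * duration_s) * fs) + 1L)
      i1 <- min(n_samp, floor((t_pk + (1 - WAVE_PEAK_FRAC) * duration_s) * fs) + 1L)
      if (i1 < i0) next
      tt <- (seq(i0, i1) - 1) / fs
      traces[e, i0:i1] <- traces[e, i0:i1] +
        eval_waveform(tt, amplitudes[e] * sigma, duration_s, t_pk)
    }
  }
  traces
}

# ---- spontaneous / propagation trials --------------------------------------

#' Simulate repeated single-AP propagation trials
#'
#' Generates `n_trials` consecutive 10 ms trial windows on the layout's
#' electrodes. In each spike trial one AP leaves the AIS `t0_ms` after the
#' trial start and propagates along the arbor at the arbor's velocity,
#' accumulating Gaussian timing jitter with variance linear in axial
#' distance; the biphasic waveform is inserted at each electrode at its
#' (sub-sample) arrival time, scaled by the electrode's amplitude, on top
#' of Gaussian noise. Electrodes outside pickup range simply carry noise.
#'
#' @param layout An [place_arbor()] layout (or pass `arbor` + `array`).
#' @param arbor,array Used to build a default layout when `layout` is NULL.
#' @param n_trials Number of 10 ms trials.
#' @param sigma Noise standard deviation (uV); `0` gives the noise-free
#'   limit with amplitudes read directly in uV.
#' @param seed Master seed; all randomness derives from it.
#' @param spike_present Logical vector (default all TRUE): which trials
#'   contain an AP. Noise-only trials carry pure noise.
#' @param trial_ms Trial window length (ms).
#' @param fs Sampling rate (Hz).
#' @param t0_ms AP time at the AIS within each trial (ms).
#' @param spatial_corr Neighbouring-channel noise correlation.
#' @param enforce_order Redraw jitter increments that would let an AP
#'   overtake itself along a branch.
#' @param traces If FALSE, skip waveform/noise synthesis and return ground
#'   truth only (fast path for kinetics studies).
#' @return List of class `propagation_sim`: `recording` (or NULL), `truth`
#'   (trial, electrode, spike_present, true_time_s, d_mm, amplitude),
#'   `layout`, `trial_starts` (s).
#' @export
simulate_propagation_trials <- function(layout = NULL, arbor = NULL,
                                        array = NULL, n_trials = 40,
                                        sigma = 1, seed = 1,
                                        spike_present = NULL, trial_ms = 10,
                                        fs = 20000, t0_ms = 3,
                                        spatial_corr = 0,
                                        enforce_order = TRUE, traces = TRUE) {
  if (is.null(layout)) {
    if (is.null(arbor) || is.null(array))
      stop("provide `layout`, or both `arbor` and `array`", call. = FALSE)
    layout <- place_arbor(arbor, array, seed = seed)
  }
  spike_present <- spike_present %||% rep(TRUE, n_trials)
  stopifnot(length(spike_present) == n_trials)
  seeds <- derive_seeds(seed, 2)
  trial_s <- trial_ms / 1000
  trial_starts <- (seq_len(n_trials) - 1) * trial_s
  rel <- sim_arrivals_rel(layout, n_trials, seed = seeds[1],
                          enforce_order = enforce_order)
  abs_t <- sweep(rel, 1, trial_starts + t0_ms / 1000, `+`)
  truth <- data.frame(
    trial = rep(seq_len(n_trials), times = nrow(layout)),
    electrode = rep(layout$electrode, each = n_trials),
    spike_present = rep(spike_present, times = nrow(layout)),
    true_time_s = ifelse(rep(spike_present, times = nrow(layout)),
                         as.vector(abs_t), NA_real_),
    d_mm = rep(layout$d_mm, each = n_trials),
    amplitude = rep(layout$amplitude, each = n_trials)
  )
  rec <- NULL
  if (traces) {
    n_samp <- round(n_trials * trial_s * fs)
    tr <- noise_or_zero(nrow(layout), n_samp, sigma, spatial_corr, seeds[2])
    tr <- insert_spikes(tr, fs, abs_t, spike_present, layout$amplitude,
                        amp_unit(sigma))
    rec <- recording(tr, fs, layout[, c("electrode", "x", "y")],
                     meta = list(seed = seed, sigma = sigma,
                                 generator = "propagation",
                                 ais_electrode = attr(layout, "ais_electrode"),
                                 trial_ms = trial_ms, t0_ms = t0_ms,
                                 n_trials = n_trials))
  }
  structure(list(recording = rec, truth = truth, layout = layout,
                 trial_starts = trial_starts),
            class = "propagation_sim")
}

# ---- voltage-sweep stimulation series --------------------------------------

#' Simulate a randomized stimulation voltage sweep
#'
#' Each voltage is applied `n_per_voltage` times in a randomized trial
#' order. Per pulse, a Bernoulli draw with the model's response probability
#' decides whether an AP is elicited; if so, its AIS time is the pulse time
#' plus the voltage-dependent activation latency plus Gaussian activation
#' jitter, and it then propagates along the arbor as in
#' [simulate_propagation_trials()]. Voltages below the modeled range never
#' elicit spikes; voltages above it always do.
#'
#' @param stim A [stimulation_model()].
#' @param voltages Stimulation voltages (mV).
#' @param n_per_voltage Trials per voltage.
#' @param pulse_ms Pulse time within each trial window (ms).
#' @inheritParams simulate_propagation_trials
#' @return List of class `stimulation_sim`: `recording` (or NULL), `truth`
#'   (trial, voltage_mV, spike_present, electrode, true_time_s — arrival
#'   relative to the pulse), `stim` table, `layout`.
#' @export
simulate_stimulation_series <- function(stim, layout = NULL, arbor = NULL,
                                        array = NULL, voltages,
                                        n_per_voltage = 60, sigma = 1,
                                        seed = 1, trial_ms = 10, fs = 20000,
                                        pulse_ms = 1, spatial_corr = 0,
                                        traces = TRUE) {
  stopifnot(inherits(stim, "stimulation_model"), n_per_voltage >= 1)
  if (is.null(layout)) {
    if (is.null(arbor) || is.null(array))
      stop("provide `layout`, or both `arbor` and `array`", call. = FALSE)
    layout <- place_arbor(arbor, array, seed = seed)
  }
  seeds <- derive_seeds(seed, 5)
  v_seq <- with_seed(seeds[1], sample(rep(voltages, each = n_per_voltage)))
  n_trials <- length(v_seq)
  p <- stim$response_prob(v_seq)
  fired <- with_seed(seeds[2], rbinom(n_trials, 1, p) == 1)
  act_us <- with_seed(seeds[3],
                      stim$latency(v_seq) + rnorm(n_trials, 0, stim$jitter(v_seq)))
  rel <- sim_arrivals_rel(layout, n_trials, seed = seeds[4])
  arr_rel <- rel + act_us * 1e-6  # relative to the pulse
  trial_s <- trial_ms / 1000
  trial_starts <- (seq_len(n_trials) - 1) * trial_s
  truth <- data.frame(
    trial = rep(seq_len(n_trials), times = nrow(layout)),
    voltage_mV = rep(v_seq, times = nrow(layout)),
    spike_present = rep(fired, times = nrow(layout)),
    electrode = rep(layout$electrode, each = n_trials),
    true_time_s = ifelse(rep(fired, times = nrow(layout)),
                         as.vector(arr_rel), NA_real_),
    d_mm = rep(layout$d_mm, each = n_trials)
  )
  stim_tab <- data.frame(trial = seq_len(n_trials),
                         time_s = trial_starts + pulse_ms / 1000,
                         voltage_mV = v_seq)
  rec <- NULL
  if (traces) {
    n_samp <- round(n_trials * trial_s * fs)
    tr <- noise_or_zero(nrow(layout), n_samp, sigma, spatial_corr, seeds[5])
    abs_t <- sweep(arr_rel, 1, stim_tab$time_s, `+`)
    tr <- insert_spikes(tr, fs, abs_t, fired, layout$amplitude,
                        amp_unit(sigma))
    rec <- recording(tr, fs, layout[, c("electrode", "x", "y")],
                     stim = stim_tab,
                     meta = list(seed = seed, sigma = sigma,
                                 generator = "stimulation",
                                 ais_electrode = attr(layout, "ais_electrode"),
                                 trial_ms = trial_ms, pulse_ms = pulse_ms))
  }
  structure(list(recording = rec, truth = truth, stim = stim_tab,
                 layout = layout),
            class = "stimulation_sim")
}

# ---- 100 Hz stimulation trains ---------------------------------------------

#' Simulate high-frequency stimulation trains
#'
#' Runs `n_episodes` episodes of `n_pulses` pulses at `rate_hz`. Pulse `k`
#' of every episode propagates with `velocity_by_pulse[k]` and accumulates
#' jitter at `jitter_by_pulse[k]`; every pulse elicits exactly one AP
#' (conduction is failure-free). Activation latency is a constant plus a
#' small Gaussian activation jitter shared by all electrodes of a trial
#' (it cancels under alignment to the proximal electrode).
#'
#' @param train A [train_model()].
#' @param act_latency_us,act_jitter_us Constant activation latency and its
#'   trial-to-trial jitter (us).
#' @inheritParams simulate_propagation_trials
#' @return List of class `train_sim`: `truth` (episode, pulse_index,
#'   electrode, true_time_s — arrival relative to the pulse, d_mm),
#'   `recording` (or NULL; episodes concatenated with a 20 ms tail),
#'   `layout`.
#' @export
simulate_train <- function(train, layout = NULL, arbor = NULL, array = NULL,
                           sigma = 1, seed = 1, act_latency_us = 150,
                           act_jitter_us = 20, fs = 20000, traces = FALSE) {
  stopifnot(inherits(train, "train_model"))
  if (is.null(layout)) {
    if (is.null(arbor) || is.null(array))
      stop("provide `layout`, or both `arbor` and `array`", call. = FALSE)
    layout <- place_arbor(arbor, array, seed = seed)
  }
  E <- train$n_episodes; K <- train$n_pulses
  n_trials <- E * K
  episode <- rep(seq_len(E), each = K)
  pulse <- rep(seq_len(K), times = E)
  seeds <- derive_seeds(seed, 3)
  rel <- sim_arrivals_rel(layout, n_trials,
                          velocity = train$velocity_by_pulse[pulse],
                          jitter_rate = train$jitter_by_pulse[pulse],
                          seed = seeds[1])
  act <- with_seed(seeds[2],
                   act_latency_us + rnorm(n_trials, 0, act_jitter_us))
  arr_rel <- rel + act * 1e-6
  truth <- data.frame(
    episode = rep(episode, times = nrow(layout)),
    pulse_index = rep(pulse, times = nrow(layout)),
    trial = rep(seq_len(n_trials), times = nrow(layout)),
    electrode = rep(layout$electrode, each = n_trials),
    true_time_s = as.vector(arr_rel),
    d_mm = rep(layout$d_mm, each = n_trials)
  )
  rec <- NULL
  if (traces) {
    ep_s <- K / train$rate_hz + 0.02
    pulse_t <- (episode - 1) * ep_s + (pulse - 1) / train$rate_hz + 0.001
    n_samp <- round(E * ep_s * fs)
    tr <- noise_or_zero(nrow(layout), n_samp, sigma, 0, seeds[3])
    abs_t <- sweep(arr_rel, 1, pulse_t, `+`)
    tr <- insert_spikes(tr, fs, abs_t, rep(TRUE, n_trials), layout$amplitude,
                        amp_unit(sigma))
    rec <- recording(tr, fs, layout[, c("electrode", "x", "y")],
                     stim = data.frame(trial = seq_len(n_trials),
                                       time_s = pulse_t, voltage_mV = NA,
                                       episode = episode, pulse_index = pulse),
                     meta = list(seed = seed, sigma = sigma,
                                 generator = "train"))
  }
  structure(list(recording = rec, truth = truth, layout = layout),
            class = "train_sim")
}

# ---- arrival tables ---------------------------------------------------------

#' Extract an arrival-time table from simulated ground truth
#'
#' Returns the tidy per-trial, per-electrode arrival table consumed by the
#' kinetics functions. With `align_electrode` set, arrival times are
#' re-referenced per trial to that electrode's arrival (the conventional
#' "alignment site"), which cancels activation latency/jitter and any
#' jitter accumulated upstream of the site.
#'
#' @param sim A simulation result (or a truth data frame).
#' @param align_electrode Optional electrode id used as alignment site.
#' @param spikes_only Drop trials without a spike (default TRUE).
#' @return Data frame with `trial`, `electrode`, `t_s` plus any grouping
#'   columns present (`voltage_mV`, `episode`, `pulse_index`).
#' @export
arrival_table <- function(sim, align_electrode = NULL, spikes_only = TRUE) {
  truth <- if (is.data.frame(sim)) sim else sim$truth
  if (spikes_only && "spike_present" %in% names(truth))
    truth <- truth[truth$spike_present, , drop = FALSE]
  keep <- intersect(c("trial", "voltage_mV", "episode", "pulse_index",
                      "electrode", "d_mm"), names(truth))
  tab <- truth[, keep, drop = FALSE]
  tab$t_s <- truth$true_time_s
  tab <- tab[!is.na(tab$t_s), , drop = FALSE]
  if (!is.null(align_electrode)) {
    ref <- tab[tab$electrode == align_electrode, c("trial", "t_s")]
    if (!nrow(ref)) stop("alignment electrode not present in the table",
                         call. = FALSE)
    names(ref)[2] <- ".t_ref"
    tab <- merge(tab, ref, by = "trial")
    tab$t_s <- tab$t_s - tab$.t_ref
    tab$.t_ref <- NULL
    attr(tab, "alignment_electrode") <- align_electrode
  }
  rownames(tab) <- NULL
  tab
}
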