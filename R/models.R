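#' Voltage-dependent excitability model for extracellular stimulation
#'
#' Encodes how a neuron responds to biphasic voltage pulses applied near its
#' AIS. Three regimes are built in: below `v_inter` the neuron never fires;
#' between `v_inter` and `v_thr` it fires in a fraction of trials that rises
#' monotonically with voltage; at and above `v_thr` it fires in 100% of
#' trials. Mean activation latency and activation jitter both decrease with
#' voltage as exponential decays in the normalized voltage
#' `vnorm = (V - v_inter)/(v_thr - v_inter)`, anchored so that the latency
#' drops by `latency_drop_inter` us across the intermediate regime
#' (vnorm 0 to 1) and by a further `latency_drop_supra` us between vnorm 1
#' and 3, and the jitter drops by `jitter_drop` us between vnorm 1 and 2.
#'
#' @param v_inter Lowest voltage (mV) eliciting at least one response.
#' @param v_thr Lowest voltage (mV) eliciting responses in 100% of trials.
#' @param step_mV Voltage step of the stimulation protocol; sets the
#'   response probability at `v_inter` to `step/(v_thr - v_inter + step)`.
#' @param latency_floor High-voltage asymptotic activation latency (us).
#' @param latency_drop_inter,latency_drop_supra Latency drops (us) across
#'   the intermediate regime and from vnorm 1 to 3.
#' @param jitter_floor High-voltage asymptotic activation jitter (us).
#' @param jitter_drop Jitter drop (us) between vnorm 1 and 2.
#' @return An object of class `stimulation_model` with function fields
#'   `response_prob(V)`, `latency(V)` and `jitter(V)` (all vectorized).
#' @export
stimulation_model <- function(v_inter = 20, v_thr = 50, step_mV = 10,
                              latency_floor = 100, latency_drop_inter = 130,
                              latency_drop_supra = 40,
                              jitter_floor = 20, jitter_drop = 12) {
  if (v_inter >= v_thr) stop("`v_inter` must be < `v_thr`", call. = FALSE)
  # latency decay L(vn) = floor + A q^vn with A(1-q) = drop_inter and
  # A(q - q^3) = drop_supra  =>  q(1+q) = drop_supra/drop_inter
  r <- latency_drop_supra / latency_drop_inter
  q <- (-1 + sqrt(1 + 4 * r)) / 2
  A <- latency_drop_inter / (1 - q)
  # jitter decay J(vn) = jfloor + B qj^vn with B qj (1 - qj) = jitter_drop
  qj <- exp(-1.25)
  B <- jitter_drop / (qj * (1 - qj))
  vnorm <- function(V) pmax(0, (V - v_inter) / (v_thr - v_inter))
  m <- list(
    v_inter = v_inter, v_thr = v_thr, step_mV = step_mV,
    response_prob = function(V) {
      p <- (V - v_inter + step_mV) / (v_thr - v_inter + step_mV)
      ifelse(V < v_inter, 0, ifelse(V >= v_thr, 1, pmin(p, 1)))
    },
    latency = function(V) latency_floor + A * q^vnorm(V),
    jitter = function(V) jitter_floor + B * qj^vnorm(V)
  )
  structure(m, class = "stimulation_model")
}

#' High-frequency stimulation-train model
#'
#' Describes activity-dependent conduction changes over repeated 100 Hz
#' stimulation: per pulse index, a conduction velocity (non-increasing) and
#' a propagation jitter rate (non-decreasing, us at 1 mm). Defaults
#' linearly interpolate through the anchor values at pulses 1, 25, 50 and
#' 100 (0.71, 0.65, 0.62, 0.57 m/s and 111, 115, 121, 124 us/mm).
#'
#' @param n_episodes Number of stimulation episodes.
#' @param n_pulses Pulses per episode.
#' @param rate_hz Pulse rate within an episode.
#' @param anchor_pulses Pulse indices of the anchors.
#' @param velocity_anchors Velocities (m/s) at the anchors.
#' @param jitter_anchors Jitter rates (us at 1 mm) at the anchors.
#' @return An object of class `train_model` with `velocity_by_pulse` and
#'   `jitter_by_pulse` vectors of length `n_pulses`.
#' @export
train_model <- function(n_episodes = 100, n_pulses = 100, rate_hz = 100,
                        anchor_pulses = c(1, 25, 50, 100),
                        velocity_anchors = c(0.71, 0.65, 0.62, 0.57),
                        jitter_anchors = c(111, 115, 121, 124)) {
  stopifnot(n_episodes >= 1, n_pulses >= 1, rate_hz > 0)
  px <- pmin(anchor_pulses, n_pulses)
  ok <- !duplicated(px)
  if (sum(ok) < 2) {
    v <- rep(velocity_anchors[1], n_pulses)
    j <- rep(jitter_anchors[1], n_pulses)
  } else {
    v <- approx(px[ok], velocity_anchors[ok], xout = seq_len(n_pulses), rule = 2)$y
    j <- approx(px[ok], jitter_anchors[ok], xout = seq_len(n_pulses), rule = 2)$y
  }
  if (any(diff(v) > 1e-12)) stop("velocity_by_pulse must be non-increasing",
                                 call. = FALSE)
  if (any(diff(j) < -1e-12)) stop("jitter_by_pulse must be non-decreasing",
                                  call. = FALSE)
  structure(list(n_episodes = as.integer(n_episodes),
                 n_pulses = as.integer(n_pulses), rate_hz = rate_hz,
                 velocity_by_pulse = v, jitter_by_pulse = j),
            class = "train_model")
}
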