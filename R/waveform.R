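#' Canonical biphasic extracellular spike waveform
#'
#' The synthetic action potential is a negative-first biphasic transient:
#' one full sine period under a Hann window. The shape is antisymmetric
#' about its midpoint, hence exactly zero-mean, and its negative peak sits
#' at one third of the duration. This shape stands in for the stereotyped
#' extracellular waveform; no biophysics is implied.
#'
#' `synth_waveform()` samples the shape on the acquisition grid and rescales
#' so that the sampled minimum equals exactly `-peak_amp`.
#'
#' @param peak_amp Magnitude of the negative peak, in units of the noise
#'   standard deviation (or uV when sigma = 1 uV).
#' @param duration_ms Waveform support in milliseconds (<= 10).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `round(duration_ms/1000 * fs)` samples.
#' @examples
#' w <- synth_waveform(5, 2, 20000)
#' length(w)  # 40
#' min(w)     # -5
#' @export
synth_waveform <- function(peak_amp, duration_ms = 2, fs = 20000) {
  if (!is.numeric(peak_amp) || length(peak_amp) != 1 || peak_amp <= 0)
    stop("`peak_amp` must be a single positive number", call. = FALSE)
  if (duration_ms <= 0 || duration_ms > 10)
    stop("`duration_ms` must lie in (0, 10]", call. = FALSE)
  n <- round(duration_ms / 1000 * fs)
  u <- (seq_len(n) - 1) / n
  w <- wave_shape(u)
  w * (peak_amp / abs(min(w)))
}

# shape on normalized time u in [0, 1): -sin(2*pi*u) * Hann(u); zero outside
wave_shape <- function(u) {
  v <- numeric(length(u))
  k <- which(u >= 0 & u < 1)
  v[k] <- -sin(2 * pi * u[k]) * 0.5 * (1 - cos(2 * pi * u[k]))
  v
}

# continuous-time peak magnitude of wave_shape (at u = 1/3)
WAVE_PEAK <- 3 * sqrt(3) / 8
# negative peak location as a fraction of the duration
WAVE_PEAK_FRAC <- 1 / 3

# Evaluate the continuous waveform (negative peak = -peak_amp at t = t_peak)
# at arbitrary times; used to insert spikes at sub-sample arrival times.
eval_waveform <- function(t_s, peak_amp, duration_s, t_peak_s = 0) {
  u <- (t_s - t_peak_s) / duration_s + WAVE_PEAK_FRAC
  peak_amp / WAVE_PEAK * wave_shape(u)
}
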