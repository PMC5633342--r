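#' Detect large AIS spikes by amplitude thresholding
#'
#' Simple negative-going threshold detection at `-threshold_factor *
#' noise_sigma`, adequate for the large axon-initial-segment signal that
#' triggers spike-triggered averaging. Each supra-threshold crossing is
#' aligned to the negative peak within `align_window_ms` after the crossing
#' (crossing-time alignment available via `align`), and triggers closer
#' than `dead_time_ms` are deduplicated, keeping the earlier one.
#'
#' @param rec A [recording()].
#' @param electrode Electrode id to threshold.
#' @param noise_sigma Noise standard deviation on that electrode (uV).
#' @param threshold_factor Threshold in noise standard deviations
#'   (default 5).
#' @param dead_time_ms Minimum separation between triggers.
#' @param align Align triggers on the negative `"peak"` (default) or the
#'   threshold `"crossing"`.
#' @param align_window_ms Search window for the peak after the crossing.
#' @return Sorted numeric vector of trigger times (s); possibly empty.
#' @export
detect_ais_spikes <- function(rec, electrode, noise_sigma,
                              threshold_factor = 5, dead_time_ms = 2,
                              align = c("peak", "crossing"),
                              align_window_ms = 0.5) {
  align <- match.arg(align)
  if (noise_sigma <= 0) stop("`noise_sigma` must be > 0", call. = FALSE)
  x <- rec$traces[rec_rows(rec, electrode), ]
  thr <- -threshold_factor * noise_sigma
  below <- x < thr
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(crossings)) return(numeric(0))
  dead <- round(dead_time_ms / 1000 * rec$fs)
  keep <- integer(0); last <- -Inf
  for (i in crossings) {
    if (i - last >= dead) { keep <- c(keep, i); last <- i }
  }
  if (align == "peak") {
    w <- round(align_window_ms / 1000 * rec$fs)
    keep <- vapply(keep, function(i) {
      j <- i:min(i + w, length(x))
      j[which.min(x[j])]
    }, 0L)
  }
  (keep - 1) / rec$fs
}

#' Spike-triggered average templates across all electrodes
#'
#' Averages trigger-aligned windows sample-wise across trials on every
#' electrode of the recording. The window places `pre_ms` before and
#' `window_ms - pre_ms` after each trigger (axonal arrivals trail the AIS,
#' so the default 3/7 ms split leaves more post-trigger context). Triggers
#' whose window would exceed the recording are dropped with a message.
#'
#' @param rec A [recording()].
#' @param trigger_times Trigger times (s), e.g. from [detect_ais_spikes()].
#' @param window_ms Window length (default 10 ms, the trial length).
#' @param pre_ms Pre-trigger part of the window.
#' @return An object of class `footprint`: electrode table, waveform matrix
#'   (electrodes x window samples), per-electrode `peaks` data frame
#'   (electrode, peak_amplitude, peak_latency_s), `n_trials`, `fs`,
#'   `pre_s`. The AIS is not located yet (see [locate_ais()]).
#' @export
spike_triggered_average <- function(rec, trigger_times, window_ms = 10,
                                    pre_ms = 3) {
  if (!length(trigger_times)) stop("no triggers supplied", call. = FALSE)
  n <- ncol(rec$traces)
  pre <- round(pre_ms / 1000 * rec$fs)
  len <- round(window_ms / 1000 * rec$fs)
  idx0 <- round(trigger_times * rec$fs) + 1L - pre
  ok <- idx0 >= 1L & (idx0 + len - 1L) <= n
  if (sum(!ok) > 0)
    message(sum(!ok), " trigger(s) dropped: window outside the recording")
  idx0 <- idx0[ok]
  if (!length(idx0)) stop("no usable triggers: all windows fall outside the recording",
                          call. = FALSE)
  acc <- matrix(0, nrow(rec$traces), len)
  for (i in idx0) acc <- acc + rec$traces[, i:(i + len - 1L), drop = FALSE]
  wave <- acc / length(idx0)
  new_footprint(rec$electrodes, wave, rec$fs, pre / rec$fs,
                n_trials = rep(length(idx0), nrow(rec$electrodes)))
}

new_footprint <- function(electrodes, wave, fs, pre_s, n_trials) {
  pk_idx <- apply(wave, 1, which.min)
  peaks <- data.frame(
    electrode = electrodes$electrode,
    peak_amplitude = pmax(0, -wave[cbind(seq_len(nrow(wave)), pk_idx)]),
    peak_latency_s = (pk_idx - 1) / fs - pre_s,
    n_trials = n_trials
  )
  structure(list(electrodes = as.data.frame(electrodes), waveforms = wave,
                 fs = fs, pre_s = pre_s, peaks = peaks),
            class = "footprint")
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint> %d electrodes, window %d samples at %g kHz, max amplitude %.3g uV\n",
              nrow(x$waveforms), ncol(x$waveforms), x$fs / 1000,
              max(x$peaks$peak_amplitude)))
  invisible(x)
}

#' Merge footprints from several electrode configurations
#'
#' High-density arrays read out only a subset of electrodes at a time;
#' scanning configurations share a few electrodes near the AIS. This
#' assembles one array-wide footprint: configurations are time-aligned by
#' the shared electrode's peak latency (integer-sample shifts), electrodes
#' appearing in several configurations get their templates averaged
#' weighted by trial counts, and the union of electrodes is returned.
#'
#' @param configs List of `footprint` objects sharing at least one common
#'   electrode.
#' @param shared_electrode Electrode id used for alignment; defaults to the
#'   electrode common to all configurations with the largest amplitude in
#'   the first configuration.
#' @return A merged `footprint`.
#' @export
assemble_footprint <- function(configs, shared_electrode = NULL) {
  stopifnot(length(configs) >= 1, all(vapply(configs, inherits, TRUE, "footprint")))
  if (length(configs) == 1) return(configs[[1]])
  common <- Reduce(intersect, lapply(configs, function(f) f$electrodes$electrode))
  if (!length(common))
    stop("configurations share no common electrode; cannot align", call. = FALSE)
  if (is.null(shared_electrode)) {
    p1 <- configs[[1]]$peaks
    cand <- p1[p1$electrode %in% common, ]
    shared_electrode <- cand$electrode[which.max(cand$peak_amplitude)]
  } else if (!shared_electrode %in% common) {
    stop("`shared_electrode` is not present in every configuration", call. = FALSE)
  }
  fs <- configs[[1]]$fs
  len <- ncol(configs[[1]]$waveforms)
  ref_lat <- configs[[1]]$peaks$peak_latency_s[
    configs[[1]]$peaks$electrode == shared_electrode]
  acc <- list()  # electrode id -> list(sum wave * w, sum w, xy)
  for (f in configs) {
    if (f$fs != fs || ncol(f$waveforms) != len)
      stop("configurations differ in sampling rate or window length", call. = FALSE)
    lat <- f$peaks$peak_latency_s[f$peaks$electrode == shared_electrode]
    shift <- round((lat - ref_lat) * fs)  # samples to advance this config
    for (r in seq_len(nrow(f$waveforms))) {
      id <- as.character(f$electrodes$electrode[r])
      w <- shift_vec(f$waveforms[r, ], -shift)
      wt <- f$peaks$n_trials[r]
      if (is.null(acc[[id]])) {
        acc[[id]] <- list(sum = w * wt, wt = wt,
                          xy = c(f$electrodes$x[r], f$electrodes$y[r]))
      } else {
        acc[[id]]$sum <- acc[[id]]$sum + w * wt
        acc[[id]]$wt <- acc[[id]]$wt + wt
      }
    }
  }
  ids <- as.integer(names(acc))
  ord <- order(ids)
  wave <- t(vapply(acc, function(a) a$sum / a$wt, numeric(len)))[ord, , drop = FALSE]
  el <- data.frame(electrode = ids[ord],
                   x = vapply(acc, function(a) a$xy[1], 0)[ord],
                   y = vapply(acc, function(a) a$xy[2], 0)[ord])
  new_footprint(el, wave, fs, configs[[1]]$pre_s,
                n_trials = vapply(acc, function(a) a$wt, 0)[ord])
}

# shift a vector by k samples (positive = delay), zero-padded
shift_vec <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  out <- numeric(n)
  if (k > 0) out[(k + 1):n] <- x[1:(n - k)]
  else out[1:(n + k)] <- x[(1 - k):n]
  out
}

#' Locate the axon initial segment electrode
#'
#' Returns the electrode with the maximal template peak amplitude; ties are
#' broken by the earliest peak latency, then the lowest electrode id —
#' the AIS co-localizes with the largest-amplitude, first-emerging
#' extracellular AP trace.
#'
#' @param fp A `footprint`.
#' @return Electrode id.
#' @export
locate_ais <- function(fp) {
  p <- fp$peaks
  if (!nrow(p)) stop("empty footprint", call. = FALSE)
  ord <- order(-p$peak_amplitude, p$peak_latency_s, p$electrode)
  p$electrode[ord[1]]
}

#' Amplitude versus Euclidean distance from the AIS
#'
#' One row per electrode: straight-line distance (um) from the AIS
#' electrode position and the template peak amplitude (uV).
#'
#' @param fp A `footprint`.
#' @param array Optional electrode array supplying coordinates; defaults to
#'   the footprint's own electrode table.
#' @param ais_electrode Optional AIS electrode id (default [locate_ais()]).
#' @return Data frame (electrode, distance_um, peak_amplitude).
#' @export
amplitude_vs_distance <- function(fp, array = NULL, ais_electrode = NULL) {
  ais_electrode <- ais_electrode %||% locate_ais(fp)
  coords <- if (is.null(array)) fp$electrodes else as.data.frame(array)
  axy <- coords[coords$electrode == ais_electrode, c("x", "y")]
  if (!nrow(axy)) stop("AIS electrode has no coordinates", call. = FALSE)
  idx <- match(fp$peaks$electrode, coords$electrode)
  d <- sqrt((coords$x[idx] - axy$x[[1]])^2 + (coords$y[idx] - axy$y[[1]])^2)
  data.frame(electrode = fp$peaks$electrode, distance_um = d,
             peak_amplitude = fp$peaks$peak_amplitude)
}
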