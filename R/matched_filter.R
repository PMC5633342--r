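#' Estimate noise statistics from spike-free data
#'
#' Computes per-electrode noise standard deviations and the spatio-temporal
#' noise covariance (all electrode pairs, lags 0..`max_lag`) from masked-in,
#' spike-free periods of a recording. Lagged products are only accumulated
#' within contiguous masked-in runs, so masking out spike epochs cannot
#' leak across gaps.
#'
#' @param rec A [recording()].
#' @param electrodes Electrode ids to model (default: all).
#' @param max_lag Maximum temporal lag in samples (the matched filter needs
#'   `max_lag >= L - 1` for a length-`L` template).
#' @param spike_free_mask Logical vector over samples; TRUE = usable noise.
#'   Default: all samples.
#' @return An object of class `noise_model`: `sigma` (uV per electrode),
#'   `ccov` (k x k x (max_lag + 1) cross-covariance array, `ccov[,,1]` is
#'   lag 0), `electrodes`, `n_samples_used`.
#' @export
estimate_noise <- function(rec, electrodes = NULL, max_lag = 0,
                           spike_free_mask = NULL) {
  electrodes <- electrodes %||% rec$electrodes$electrode
  X <- rec$traces[rec_rows(rec, electrodes), , drop = FALSE]
  n <- ncol(X)
  mask <- spike_free_mask %||% rep(TRUE, n)
  stopifnot(length(mask) == n)
  runs <- mask_runs(mask)
  runs <- runs[runs[, 2] - runs[, 1] + 1 > max_lag, , drop = FALSE]
  n_used <- if (nrow(runs)) sum(runs[, 2] - runs[, 1] + 1) else 0
  if (n_used < 10 * (max_lag + 1))
    stop(sprintf("insufficient spike-free data: %d samples, need >= %d",
                 n_used, 10 * (max_lag + 1)), call. = FALSE)
  k <- nrow(X)
  ccov <- array(0, c(k, k, max_lag + 1))
  cnt <- numeric(max_lag + 1)
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, 1]; b <- runs[r, 2]
    seg <- X[, a:b, drop = FALSE]
    seg <- seg - rowMeans(seg)
    m <- ncol(seg)
    for (lag in 0:max_lag) {
      ccov[, , lag + 1] <- ccov[, , lag + 1] +
        seg[, 1:(m - lag), drop = FALSE] %*% t(seg[, (1 + lag):m, drop = FALSE])
      cnt[lag + 1] <- cnt[lag + 1] + (m - lag)
    }
  }
  for (lag in 0:max_lag) ccov[, , lag + 1] <- ccov[, , lag + 1] / cnt[lag + 1]
  sigma <- sqrt(diag(matrix(ccov[, , 1], k, k)))
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    stop("degenerate noise: zero variance on at least one electrode",
         call. = FALSE)
  structure(list(sigma = sigma, ccov = ccov, electrodes = electrodes,
                 max_lag = max_lag, n_samples_used = n_used),
            class = "noise_model")
}

# start/end indices of TRUE runs in a logical vector
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(starts, ends)[r$values, , drop = FALSE]
}

#' Group electrodes into local detection clusters
#'
#' For every electrode whose template peak amplitude exceeds `floor_amp`
#' (default two noise standard deviations), forms the group of that
#' electrode and its `k - 1` nearest neighbours (Euclidean distance, ties
#' broken by electrode id) among the footprint's electrodes. Groups may
#' overlap; with `k = 1` each group is a singleton.
#'
#' @param fp A `footprint`.
#' @param array Electrode array (coordinates); defaults to the footprint's
#'   electrode table.
#' @param k Group size (1 to 6 in the standard protocol).
#' @param noise_sigma Noise standard deviation used for the seed floor.
#' @param floor_amp Seed amplitude floor in uV (default `2 * noise_sigma`).
#' @return Named list of integer electrode-id vectors (name = seed
#'   electrode); each vector starts with the seed.
#' @export
group_electrodes <- function(fp, array = NULL, k = 3, noise_sigma = 1,
                             floor_amp = NULL) {
  stopifnot(k >= 1)
  floor_amp <- floor_amp %||% (2 * noise_sigma)
  coords <- if (is.null(array)) fp$electrodes else as.data.frame(array)
  idx <- match(fp$peaks$electrode, coords$electrode)
  xy <- cbind(coords$x[idx], coords$y[idx])
  ids <- fp$peaks$electrode
  seeds <- ids[fp$peaks$peak_amplitude >= floor_amp]
  if (k > length(ids)) stop(sprintf("k = %d exceeds the %d available electrodes",
                                    k, length(ids)), call. = FALSE)
  out <- lapply(seeds, function(s) {
    i <- which(ids == s)
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    ord <- order(d2, ids)
    ids[ord[seq_len(k)]]
  })
  names(out) <- as.character(seeds)
  out
}

#' Build a noise-whitened multi-electrode matched filter
#'
#' The optimal linear (finite-impulse-response) detector for a known
#' transient in Gaussian noise: stack the group's templates into one
#' spatio-temporal vector `s`, solve `C w = s` against the spatio-temporal
#' noise covariance `C` (block Toeplitz from the lagged cross-covariances,
#' diagonally loaded by `ridge * mean(sigma^2)` for positive definiteness)
#' and use `w` as per-electrode impulse responses whose outputs are summed
#' across the group. With identity covariance this reduces to plain
#' template correlation scaled by `1/sigma^2`. The filter length is the
#' template support where any group electrode exceeds
#' `support_floor * sigma`, clamped to `[min_ms, max_ms]`.
#'
#' @param fp A `footprint` providing the templates.
#' @param group Integer vector of electrode ids (1-6), seed first.
#' @param noise A `noise_model` covering (at least) the group electrodes
#'   with `max_lag >= L - 1`; shorter lags are treated as zero covariance.
#' @param whitening `"full"` spatio-temporal covariance (default) or
#'   `"spatial"` (lag-0 covariance only, white in time).
#' @param ridge Diagonal loading factor.
#' @param support_floor,min_ms,max_ms Template support truncation controls.
#' @return An object of class `group_filter`: `electrodes`, `coefficients`
#'   (k x L), `template` (k x L), `expected_peak`, `output_noise_var`,
#'   `threshold` (filled by [optimal_threshold()]), `peak_offset` (samples
#'   from template start to its negative peak), `t_start_s` (template start
#'   relative to the footprint trigger), `fs`.
#' @export
build_matched_filter <- function(fp, group, noise,
                                 whitening = c("full", "spatial"),
                                 ridge = 1e-3, support_floor = 0.5,
                                 min_ms = 1, max_ms = 3) {
  whitening <- match.arg(whitening)
  stopifnot(length(group) >= 1, length(group) <= 6)
  rows <- match(group, fp$peaks$electrode)
  if (anyNA(rows)) stop("group electrode(s) missing from footprint", call. = FALSE)
  S_full <- fp$waveforms[rows, , drop = FALSE]
  nrows <- match(group, noise$electrodes)
  if (anyNA(nrows)) stop("group electrode(s) missing from noise model", call. = FALSE)
  sig <- noise$sigma[nrows]
  # truncate to the union support above support_floor * sigma
  above <- which(colSums(abs(S_full) > support_floor * sig) > 0)
  fs <- fp$fs
  Lmin <- round(min_ms / 1000 * fs); Lmax <- round(max_ms / 1000 * fs)
  if (!length(above)) above <- which.min(S_full[1, ])
  i0 <- min(above); i1 <- max(above)
  if (i1 - i0 + 1 < Lmin) {
    pad <- Lmin - (i1 - i0 + 1)
    i0 <- max(1, i0 - ceiling(pad / 2))
    i1 <- min(ncol(S_full), i0 + Lmin - 1)
    i0 <- max(1, i1 - Lmin + 1)
  }
  if (i1 - i0 + 1 > Lmax) {
    # keep the window of maximal energy
    en <- colSums(S_full[, i0:i1, drop = FALSE]^2)
    cs <- c(0, cumsum(en))
    win <- which.max(cs[(Lmax + 1):length(cs)] - cs[1:(length(cs) - Lmax)])
    i1 <- i0 + win + Lmax - 2
    i0 <- i0 + win - 1
  }
  S <- S_full[, i0:i1, drop = FALSE]
  L <- ncol(S)
  k <- nrow(S)
  s <- as.vector(t(S))  # electrode-major blocks of length L
  if (whitening == "spatial") {
    C0 <- matrix(noise$ccov[nrows, nrows, 1], k, k)
    C0 <- C0 + ridge * mean(sig^2) * diag(k)
    Wm <- solve(C0, S)  # k x L
    w <- as.vector(t(Wm))
    Cw <- as.vector(t(C0 %*% Wm))
  } else {
    C <- st_covariance(noise, nrows, L)
    C <- C + ridge * mean(sig^2) * diag(k * L)
    ch <- tryCatch(chol(C), error = function(e)
      stop("noise covariance is singular even after diagonal loading",
           call. = FALSE))
    w <- backsolve(ch, forwardsolve(t(ch), s))
    Cw <- as.vector(C %*% w)
  }
  expected_peak <- sum(s * w)
  if (expected_peak <= 0)
    stop("degenerate template: non-positive expected filter peak", call. = FALSE)
  output_noise_var <- sum(w * Cw)
  Wm <- matrix(w, k, L, byrow = TRUE)
  # align the output to the seed (first) electrode's template peak, so event
  # times report the arrival at the seed electrode even when group members
  # sit at different axial positions
  pk <- which.min(S[1, ])
  f <- structure(list(electrodes = group, coefficients = Wm, template = S,
                      expected_peak = expected_peak,
                      output_noise_var = output_noise_var,
                      threshold = NA_real_, peak_offset = pk - 1L,
                      t_start_s = (i0 - 1) / fs - fp$pre_s, fs = fs,
                      whitening = whitening),
                 class = "group_filter")
  f$threshold <- optimal_threshold(f)
  f
}

# block-Toeplitz spatio-temporal covariance for the given noise-model rows
st_covariance <- function(noise, nrows, L) {
  k <- length(nrows)
  max_lag <- noise$max_lag
  C <- matrix(0, k * L, k * L)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    # r_ab(lag) = E[x_a(t) x_b(t + lag)]; lags beyond max_lag taken as 0
    block <- matrix(0, L, L)
    for (lag in 0:min(L - 1, max_lag)) {
      rpos <- noise$ccov[nrows[a], nrows[b], lag + 1]
      rneg <- noise$ccov[nrows[b], nrows[a], lag + 1]
      if (lag == 0) {
        diag(block) <- rpos
      } else {
        block[col(block) - row(block) == lag] <- rpos
        block[row(block) - col(block) == lag] <- rneg
      }
    }
    C[((a - 1) * L + 1):(a * L), ((b - 1) * L + 1):(b * L)] <- block
  }
  (C + t(C)) / 2
}

#' Analytic detection threshold for a matched filter
#'
#' Bayes-optimal threshold for deciding between "template present" and
#' "noise only" from the filter output, both Gaussian with equal variance:
#' the midpoint `expected_peak / 2` at equal priors, shifted by
#' `(output_noise_var / expected_peak) * log(prior_ratio)` when the noise
#' hypothesis is `prior_ratio` times more likely.
#'
#' @param filter A `group_filter`.
#' @param prior_ratio Prior odds of noise versus spike (default 1).
#' @return Threshold in filter-output units.
#' @export
optimal_threshold <- function(filter, prior_ratio = 1) {
  stopifnot(prior_ratio > 0)
  filter$expected_peak / 2 +
    (filter$output_noise_var / filter$expected_peak) * log(prior_ratio)
}

#' Convolve a recording with a group filter and sum across electrodes
#'
#' Correlates each group electrode's trace with its impulse response and
#' sums the outputs. The output time axis is aligned to the template's
#' negative peak: a noise-free trace containing the template yields
#' `expected_peak` exactly at the sample where the template peak was
#' inserted. Samples too close to the edges for a full window are zero.
#'
#' @param x A [recording()] or a plain `k x n` matrix ordered as
#'   `filter$electrodes`.
#' @param filter A `group_filter`.
#' @return Numeric vector of length `n` of filter-output scores, with
#'   attribute `valid` giving the first and last meaningful sample.
#' @export
convolve_and_sum <- function(x, filter) {
  X <- if (inherits(x, "recording"))
    x$traces[rec_rows(x, filter$electrodes), , drop = FALSE]
  else as.matrix(x)
  if (nrow(X) != length(filter$electrodes))
    stop("trace matrix does not match the filter's electrode count", call. = FALSE)
  L <- ncol(filter$coefficients)
  n <- ncol(X)
  if (n < L) stop("trace shorter than the filter", call. = FALSE)
  m <- n - L + 1
  z <- numeric(m)
  for (e in seq_len(nrow(X))) {
    # embed() rows are windows in reverse time order
    z <- z + as.vector(embed(X[e, ], L) %*% rev(filter$coefficients[e, ]))
  }
  y <- numeric(n)
  p <- filter$peak_offset
  y[(1 + p):(m + p)] <- z
  attr(y, "valid") <- c(1 + p, m + p)
  y
}

#' Detect supra-threshold events in a filter output
#'
#' One event per supra-threshold excursion (the local maximum within the
#' excursion); events closer than `dead_time_ms` are merged keeping the
#' larger peak.
#'
#' @param y Filter output from [convolve_and_sum()].
#' @param threshold Detection threshold (> 0); default: the filter's.
#' @param fs Sampling rate (Hz).
#' @param dead_time_ms Merge window.
#' @param filter Optional `group_filter` supplying threshold and fs.
#' @return Data frame (`sample`, `time_s`, `score`), possibly empty.
#' @export
detect_events <- function(y, threshold = NULL, fs = NULL, dead_time_ms = 1,
                          filter = NULL) {
  threshold <- threshold %||% filter$threshold
  fs <- fs %||% filter$fs
  if (is.null(threshold) || threshold <= 0)
    stop("`threshold` must be > 0", call. = FALSE)
  above <- y >= threshold
  if (!any(above)) return(data.frame(sample = integer(0), time_s = numeric(0),
                                     score = numeric(0)))
  runs <- mask_runs(above)
  peak <- apply(runs, 1, function(r) {
    j <- r[1]:r[2]
    j[which.max(y[j])]
  })
  score <- y[peak]
  ord <- order(peak)
  peak <- peak[ord]; score <- score[ord]
  dead <- round(dead_time_ms / 1000 * fs)
  keep <- rep(TRUE, length(peak))
  i <- 1
  while (i < length(peak)) {
    j <- i + 1
    while (j <= length(peak) && keep[j] == TRUE && peak[j] - peak[i] < dead) {
      if (score[j] > score[i]) { keep[i] <- FALSE; i <- j }
      else keep[j] <- FALSE
      j <- j + 1
    }
    i <- j
  }
  data.frame(sample = peak[keep], time_s = (peak[keep] - 1) / fs,
             score = score[keep])
}

#' Whittaker-Shannon (sinc) upsampling
#'
#' Band-limited interpolation by Fourier zero-padding: exact for signals
#' whose content lies below the Nyquist rate and is periodic in the window
#' (e.g. a sinusoid with an integer number of cycles), and accurate in the
#' interior of well-behaved windows. Returns the signal resampled on a grid
#' `factor` times finer, starting at the first original sample.
#'
#' @param x Numeric vector.
#' @param factor Integer upsampling factor (default 10, i.e. 20 kHz ->
#'   200 kHz).
#' @return Numeric vector of length `length(x) * factor`.
#' @export
sinc_interp <- function(x, factor = 10) {
  n <- length(x)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(x)
  X <- fft(x)
  m <- n * factor
  Y <- complex(m)
  h <- floor(n / 2)
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h >= 1) Y[(m - (n - h - 2)):m] <- X[(h + 2):n]
  if (n %% 2 == 0) {  # split the Nyquist bin symmetrically
    Y[h + 1] <- X[h + 1] / 2
    Y[m - h + 1] <- X[h + 1] / 2
  }
  Re(fft(Y, inverse = TRUE)) / n  # ifft scaling (1/m) times amplitude (m/n)
}

#' Sub-sample refinement of an event time
#'
#' Interpolates the filter output around an event peak with a Hann-windowed
#' sinc kernel on a grid `upsample` times finer (default 10, 200 kHz
#' effective) and returns the interpolated argmax. Events too close to the
#' trace edge fall back to the sample-resolution time with attribute
#' `refined = FALSE`.
#'
#' @param y Filter output vector.
#' @param event_sample Peak sample index (from [detect_events()]).
#' @param fs Sampling rate (Hz).
#' @param upsample Interpolation factor.
#' @param half_window_ms Half-width of the interpolation window.
#' @return Event time in seconds with attribute `refined`.
#' @export
refine_time <- function(y, event_sample, fs, upsample = 10,
                        half_window_ms = 0.5) {
  hw <- round(half_window_ms / 1000 * fs)
  n <- length(y)
  if (event_sample - hw < 1 || event_sample + hw > n) {
    t <- (event_sample - 1) / fs
    attr(t, "refined") <- FALSE
    return(t)
  }
  j <- (event_sample - hw):(event_sample + hw)
  seg <- y[j]
  # fine grid spanning +/- 1 sample around the peak
  tf <- seq(-1, 1, by = 1 / upsample)
  # Hann-windowed sinc kernel over the segment
  rel <- outer(tf + hw, seq_along(seg) - 1, `-`)  # fine time - sample pos
  win_half <- hw + 1
  kern <- sinc(rel) * hann_taper(rel, win_half)
  vals <- as.vector(kern %*% seg)
  t <- (event_sample - 1 + tf[which.max(vals)]) / fs
  attr(t, "refined") <- TRUE
  t
}

sinc <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))

hann_taper <- function(u, half) ifelse(abs(u) >= half, 0,
                                       0.5 * (1 + cos(pi * u / half)))
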