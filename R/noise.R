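#' Generate multichannel Gaussian recording noise
#'
#' Zero-mean Gaussian noise per electrode. With `spatial_corr = 0` the
#' channels are independent with standard deviation `sigma`. With
#' `spatial_corr = c` the channels follow a first-order spatial
#' autoregression in channel order, so the correlation between neighbouring
#' channels is exactly `c` (and `c^k` at channel distance `k`); each
#' channel's marginal standard deviation remains `sigma`.
#'
#' @param n_electrodes,n_samples Trace dimensions.
#' @param sigma Noise standard deviation in uV.
#' @param spatial_corr Neighbouring-channel correlation in `[0, 1)`.
#' @param seed Integer seed; identical seeds give bit-identical traces.
#' @return `n_electrodes x n_samples` numeric matrix.
#' @export
synth_noise <- function(n_electrodes, n_samples, sigma = 1, spatial_corr = 0,
                        seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (spatial_corr < 0 || spatial_corr >= 1)
    stop("`spatial_corr` must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    z <- matrix(rnorm(n_electrodes * n_samples), n_electrodes, n_samples)
    if (spatial_corr > 0 && n_electrodes > 1) {
      # AR(1) across channels: x_1 = z_1; x_i = c x_{i-1} + sqrt(1-c^2) z_i
      s <- sqrt(1 - spatial_corr^2)
      for (i in 2:n_electrodes)
        z[i, ] <- spatial_corr * z[i - 1, ] + s * z[i, ]
    }
    sigma * z
  })
}
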