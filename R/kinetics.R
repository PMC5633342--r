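#' Classify stimulation voltages into excitability regimes
#'
#' Applies the standard regime definitions: `v_inter` is the lowest voltage
#' with any response, `v_thr` the lowest voltage with responses in 100% of
#' trials; voltages below `v_inter` are `sub`-threshold, voltages in
#' `[v_inter, v_thr)` `intermediate`, and voltages at or above `v_thr`
#' `supra`-threshold. Non-monotone response fractions are retained but
#' flagged.
#'
#' @param voltages Stimulation voltages (mV).
#' @param responses Response fractions in `[0, 1]`, or response counts if
#'   `n_trials` is given.
#' @param n_trials Optional trials per voltage (scalar or vector).
#' @return An `excitability_profile`: data frame (voltage_mV,
#'   response_fraction, regime) with attributes `v_inter`, `v_thr`,
#'   `monotone`.
#' @export
classify_regimes <- function(voltages, responses, n_trials = NULL) {
  stopifnot(length(voltages) == length(responses))
  frac <- if (is.null(n_trials)) responses else responses / n_trials
  if (any(frac < 0 | frac > 1)) stop("response fractions must lie in [0, 1]",
                                     call. = FALSE)
  ord <- order(voltages)
  voltages <- voltages[ord]; frac <- frac[ord]
  if (!any(frac == 1))
    stop("no voltage elicited responses in 100% of trials: stimulation threshold undefined",
         call. = FALSE)
  v_thr <- min(voltages[frac == 1])
  v_inter <- min(voltages[frac > 0])
  regime <- ifelse(voltages < v_inter, "sub",
                   ifelse(voltages < v_thr, "intermediate", "supra"))
  monotone <- !is.unsorted(frac)
  if (!monotone)
    warning("response fractions are not monotone in voltage", call. = FALSE)
  structure(data.frame(voltage_mV = voltages, response_fraction = frac,
                       regime = regime),
            v_inter = v_inter, v_thr = v_thr, monotone = monotone,
            class = c("excitability_profile", "data.frame"))
}

#' Normalize a stimulation voltage to the intermediate regime
#'
#' `vnorm = (V - v_inter) / (v_thr - v_inter)`: the onset of the
#' intermediate regime maps to 0 and the stimulation threshold to 1;
#' supra-threshold voltages exceed 1.
#'
#' @param V Voltage(s) in mV.
#' @param v_inter,v_thr Regime bounds in mV (`v_thr > v_inter`), or pass an
#'   `excitability_profile` as `v_inter`.
#' @return Normalized voltage(s).
#' @export
normalize_voltage <- function(V, v_inter, v_thr = NULL) {
  if (inherits(v_inter, "excitability_profile")) {
    v_thr <- attr(v_inter, "v_thr")
    v_inter <- attr(v_inter, "v_inter")
  }
  if (v_thr <= v_inter)
    stop("normalization undefined: `v_thr` must exceed `v_inter`", call. = FALSE)
  (V - v_inter) / (v_thr - v_inter)
}

#' Decompose arrival times into activation latency and jitter
#'
#' Arrival times are modelled as activation latency plus propagation time,
#' and their standard deviation as activation jitter plus propagation
#' jitter. Activation at the largest applied voltage is taken as immediate,
#' so the propagation time is the mean arrival at that voltage; per-voltage
#' activation latency is the mean arrival minus that propagation time. The
#' propagation-jitter reference is the minimum arrival-time standard
#' deviation over voltages, and activation jitter is the per-voltage
#' arrival std minus that reference (literal std subtraction; set
#' `jitter_domain = "variance"` for the quadrature alternative
#' `sqrt(J_arrival^2 - J_prop^2)`).
#'
#' @param arrivals Arrival table with columns `trial`, `voltage_mV`, `t_s`
#'   (see [arrival_table()]); arrivals referenced to the stimulation pulse.
#' @param electrode Electrode to analyse when several are present
#'   (default: the single one, or an error).
#' @param min_trials Voltages with fewer trials are excluded with a
#'   message.
#' @param jitter_domain `"std"` (default) or `"variance"`.
#' @return A `latency_decomposition` data frame per voltage:
#'   `voltage_mV`, `n`, `t_arrival_us`, `t_activation_us`, `j_arrival_us`,
#'   `j_activation_us`; attributes `t_propagation_us`, `j_propagation_us`.
#' @export
decompose_latency_jitter <- function(arrivals, electrode = NULL,
                                     min_trials = 2,
                                     jitter_domain = c("std", "variance")) {
  jitter_domain <- match.arg(jitter_domain)
  if ("electrode" %in% names(arrivals)) {
    els <- unique(arrivals$electrode)
    if (is.null(electrode)) {
      if (length(els) > 1)
        stop("several electrodes present; pick one with `electrode`",
             call. = FALSE)
      electrode <- els
    }
    arrivals <- arrivals[arrivals$electrode == electrode, , drop = FALSE]
  }
  if (!all(c("voltage_mV", "t_s") %in% names(arrivals)))
    stop("arrival table needs `voltage_mV` and `t_s` columns", call. = FALSE)
  sp <- split(arrivals$t_s, arrivals$voltage_mV)
  n <- vapply(sp, length, 0L)
  drop <- n < min_trials
  if (any(drop))
    message(sum(drop), " voltage group(s) excluded (< ", min_trials, " trials)")
  sp <- sp[!drop]
  if (length(sp) < 2)
    stop("need >= 2 voltages with enough trials", call. = FALSE)
  v <- as.numeric(names(sp))
  mean_us <- vapply(sp, mean, 0) * 1e6
  sd_us <- vapply(sp, sd, 0) * 1e6
  v_max <- max(v)
  t_prop <- mean_us[v == v_max]
  j_prop <- min(sd_us)
  j_act <- if (jitter_domain == "std") sd_us - j_prop
           else sqrt(pmax(0, sd_us^2 - j_prop^2))
  out <- data.frame(voltage_mV = v, n = as.integer(n[!drop]),
                    t_arrival_us = unname(mean_us),
                    t_activation_us = unname(mean_us - t_prop),
                    j_arrival_us = unname(sd_us),
                    j_activation_us = unname(j_act))
  rownames(out) <- NULL
  structure(out, t_propagation_us = unname(t_prop),
            j_propagation_us = unname(j_prop), electrode = electrode,
            jitter_domain = jitter_domain,
            class = c("latency_decomposition", "data.frame"))
}

#' Axial distances of electrodes along a branch polyline
#'
#' Projects each electrode onto the branch polyline and returns the
#' cumulative arc length (mm) at the projection point — the distance an AP
#' travels along the branch with all its turns, as opposed to the Euclidean
#' distance. Electrodes farther than `cutoff` from the polyline are
#' excluded with a message.
#'
#' @param poly n x 2 matrix of polyline vertices (um).
#' @param electrodes Data frame with `electrode`, `x`, `y` (um).
#' @param cutoff Maximum perpendicular distance (um); default one standard
#'   pitch (17.8).
#' @return A `branch_path` data frame (electrode, d_mm, offset_um) ordered
#'   by axial distance.
#' @export
axial_distance <- function(poly, electrodes, cutoff = 17.8) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 2) stop("polyline needs >= 2 points", call. = FALSE)
  pr <- project_onto_polyline(cbind(electrodes$x, electrodes$y), poly)
  keep <- pr$dist <= cutoff
  if (any(!keep))
    message(sum(!keep), " electrode(s) farther than ", cutoff,
            " um from the path excluded")
  out <- data.frame(electrode = electrodes$electrode[keep],
                    d_mm = pr$arc[keep] / 1000,
                    offset_um = pr$dist[keep])
  out <- out[order(out$d_mm, out$electrode), ]
  rownames(out) <- NULL
  structure(out, class = c("branch_path", "data.frame"))
}

# internal: per-electrode mean/var of aligned arrivals joined to distances
summarize_arrivals <- function(arrivals, path) {
  if (inherits(path, "arbor_layout") || (!inherits(path, "branch_path") &&
      all(c("electrode", "d_mm") %in% names(path))))
    path <- data.frame(electrode = path$electrode, d_mm = path$d_mm)
  sp <- split(arrivals$t_s, arrivals$electrode)
  st <- data.frame(electrode = as.numeric(names(sp)),
                   n = vapply(sp, length, 0L),
                   mean_s = vapply(sp, mean, 0),
                   var_s2 = vapply(sp, function(z)
                     if (length(z) > 1) var(z) else 0, 0))
  m <- merge(path, st, by = "electrode")
  m[order(m$d_mm), ]
}

#' Fit propagation velocity by linear regression
#'
#' Ordinary least squares of per-electrode mean arrival time against axial
#' distance along the branch; the velocity is the reciprocal slope, with
#' its standard error propagated from the slope standard error.
#'
#' @param arrivals Arrival table (`electrode`, `t_s`), typically aligned to
#'   the proximal electrode via [arrival_table()].
#' @param path A [axial_distance()] result or any table with `electrode`
#'   and `d_mm`.
#' @return A `propagation_fit` list: `velocity_mps`, `velocity_se_mps`,
#'   `slope_s_per_mm`, `n_electrodes`, `fit` (the `lm`).
#' @export
velocity_fit <- function(arrivals, path) {
  m <- summarize_arrivals(arrivals, path)
  if (nrow(m) < 3) stop("need >= 3 electrodes on the path", call. = FALSE)
  fit <- lm(mean_s ~ d_mm, data = m)
  slope <- coef(fit)[["d_mm"]]
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive fitted slope: arrival times do not increase along the path (mis-ordered path?)",
         call. = FALSE)
  se <- summary(fit)$coefficients["d_mm", "Std. Error"]
  structure(list(velocity_mps = 1e-3 / slope,
                 velocity_se_mps = 1e-3 * se / slope^2,
                 slope_s_per_mm = slope, n_electrodes = nrow(m), fit = fit),
            class = "propagation_fit")
}

#' Fit propagation-jitter accumulation by through-origin regression
#'
#' If each axonal segment adds independent timing noise, the arrival-time
#' variance grows linearly with axial distance from the alignment site
#' (where it is zero by construction). Fits per-electrode arrival-time
#' variance against axial distance with a forced zero intercept; the
#' square root of the slope is the propagation jitter per unit length
#' (us at 1 mm).
#'
#' @param arrivals Aligned arrival table (`electrode`, `t_s`).
#' @param path Table with `electrode` and `d_mm` (distances measured from
#'   the alignment site).
#' @param min_trials Electrodes with fewer trials are dropped.
#' @param weighted If TRUE, weight electrodes by the inverse chi-square
#'   variance of their variance estimates (`2 sigma^4/(n-1)`).
#' @return A `propagation_fit` list: `jitter_rate_us_mm`,
#'   `variance_slope_us2_mm`, `n_electrodes`, `fit`.
#' @export
jitter_fit <- function(arrivals, path, min_trials = 2, weighted = FALSE) {
  m <- summarize_arrivals(arrivals, path)
  m <- m[m$n >= min_trials | m$d_mm == 0, , drop = FALSE]
  if (nrow(m) < 3) stop("need >= 3 electrodes on the path", call. = FALSE)
  m$var_us2 <- m$var_s2 * 1e12
  if (weighted) {
    w <- ifelse(m$var_us2 > 0, (m$n - 1) / (2 * pmax(m$var_us2, 1e-12)^2), 1)
    fit <- lm(var_us2 ~ 0 + d_mm, data = m, weights = w)
  } else {
    fit <- lm(var_us2 ~ 0 + d_mm, data = m)
  }
  slope <- coef(fit)[["d_mm"]]
  if (slope < 0) {
    warning("negative fitted variance slope; jitter rate reported as 0",
            call. = FALSE)
    rate <- 0
  } else rate <- sqrt(slope)
  structure(list(jitter_rate_us_mm = rate, variance_slope_us2_mm = slope,
                 n_electrodes = nrow(m), fit = fit),
            class = "propagation_fit")
}

#' @export
print.propagation_fit <- function(x, ...) {
  if (!is.null(x$velocity_mps))
    cat(sprintf("<propagation_fit> velocity %.3g +/- %.2g m/s (%d electrodes)\n",
                x$velocity_mps, x$velocity_se_mps, x$n_electrodes))
  else
    cat(sprintf("<propagation_fit> jitter rate %.3g us at 1 mm (%d electrodes)\n",
                x$jitter_rate_us_mm, x$n_electrodes))
  invisible(x)
}

#' Per-pulse-index velocity and jitter over stimulation trains
#'
#' Groups train trials by their pulse index within the episode, computes a
#' velocity fit and a jitter fit per requested index across all episodes,
#' and reports the percentage change between the first and last requested
#' index.
#'
#' @param arrivals Aligned arrival table with a `pulse_index` column (see
#'   [arrival_table()] on a [simulate_train()] result).
#' @param path Table with `electrode` and `d_mm`.
#' @param pulse_indices Pulse indices to analyse (default c(1, 25, 50,
#'   100)).
#' @return A `train_analysis` data frame (pulse_index, n_episodes,
#'   velocity_mps, velocity_se_mps, jitter_rate_us_mm) with attributes
#'   `velocity_change_pct` and `jitter_change_pct` (first vs last index).
#' @export
train_analysis <- function(arrivals, path, pulse_indices = c(1, 25, 50, 100)) {
  if (!"pulse_index" %in% names(arrivals))
    stop("arrival table needs a `pulse_index` column", call. = FALSE)
  pulse_indices <- sort(unique(pulse_indices))
  avail <- unique(arrivals$pulse_index)
  miss <- setdiff(pulse_indices, avail)
  if (length(miss)) {
    message("pulse index(es) ", paste(miss, collapse = ", "),
            " absent; analysing the rest")
    pulse_indices <- setdiff(pulse_indices, miss)
  }
  rows <- lapply(pulse_indices, function(k) {
    sub <- arrivals[arrivals$pulse_index == k, , drop = FALSE]
    vf <- velocity_fit(sub, path)
    jf <- jitter_fit(sub, path)
    data.frame(pulse_index = k,
               n_episodes = length(unique(sub$trial)),
               velocity_mps = vf$velocity_mps,
               velocity_se_mps = vf$velocity_se_mps,
               jitter_rate_us_mm = jf$jitter_rate_us_mm)
  })
  out <- do.call(rbind, rows)
  k1 <- 1; kn <- nrow(out)
  structure(out,
            velocity_change_pct =
              100 * (out$velocity_mps[k1] - out$velocity_mps[kn]) /
              out$velocity_mps[k1],
            jitter_change_pct =
              100 * (out$jitter_rate_us_mm[kn] - out$jitter_rate_us_mm[k1]) /
              out$jitter_rate_us_mm[k1],
            class = c("train_analysis", "data.frame"))
}
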