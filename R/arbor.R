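#' Define a branching axonal arbor
#'
#' An arbor is a set of polylines in the array plane: branch 1 starts at the
#' axon initial segment (AIS); every later branch must start on an earlier
#' branch (within `tol` micrometres). Action potentials propagate from the
#' AIS at `velocity` and accumulate arrival-time noise as a white Gaussian
#' process: the variance of the accumulated jitter after `d` mm of path is
#' `jitter_rate^2 * d`, with `jitter_rate` expressed as the jitter standard
#' deviation (us) after exactly 1 mm.
#'
#' @param ais_xy Numeric length-2: AIS position (um).
#' @param branches List of n x 2 matrices of polyline vertices (um).
#' @param velocity Conduction velocity in m/s (> 0).
#' @param jitter_rate Propagation jitter in us at 1 mm of path (>= 0).
#' @param tol Attachment tolerance in um.
#' @return An object of class `arbor_model`.
#' @export
arbor_model <- function(ais_xy, branches, velocity = 0.7, jitter_rate = 100,
                        tol = 1e-6) {
  stopifnot(is.numeric(ais_xy), length(ais_xy) == 2, is.list(branches),
            length(branches) >= 1)
  if (velocity <= 0) stop("`velocity` must be > 0 (m/s)", call. = FALSE)
  if (jitter_rate < 0) stop("`jitter_rate` must be >= 0", call. = FALSE)
  branches <- lapply(branches, function(b) {
    b <- as.matrix(b)
    if (ncol(b) != 2 || nrow(b) < 2) stop("each branch needs >= 2 (x, y) points",
                                          call. = FALSE)
    unname(b)
  })
  if (sqrt(sum((branches[[1]][1, ] - ais_xy)^2)) > max(tol, 1e-6))
    stop("branch 1 must start at the AIS position", call. = FALSE)
  # resolve parentage: each non-root branch attaches to the closest point on
  # an earlier branch; record the parent's arc position of the attachment
  parent <- integer(length(branches)); d_attach <- numeric(length(branches))
  parent[1] <- 0L; d_attach[1] <- 0
  if (length(branches) > 1) {
    for (i in 2:length(branches)) {
      p0 <- branches[[i]][1, , drop = FALSE]
      best <- NULL
      for (j in seq_len(i - 1)) {
        pr <- project_onto_polyline(p0, branches[[j]])
        if (is.null(best) || pr$dist < best$dist) best <- c(pr, list(branch = j))
      }
      if (best$dist > max(tol, 1e-3))
        stop(sprintf("branch %d does not start on a parent branch (gap %.3g um)",
                     i, best$dist), call. = FALSE)
      parent[i] <- best$branch
      d_attach[i] <- best$arc  # um along the parent branch, local
    }
  }
  structure(list(ais_xy = as.numeric(ais_xy), branches = branches,
                 velocity = velocity, jitter_rate = jitter_rate,
                 parent = parent, d_attach_local = d_attach),
            class = "arbor_model")
}

#' @export
print.arbor_model <- function(x, ...) {
  len <- sum(vapply(x$branches, polyline_length, 0))
  cat(sprintf("<arbor_model> %d branch(es), total path %.3g um, v = %.3g m/s, jitter %.3g us/mm^(1/2 scale at 1 mm)\n",
              length(x$branches), len, x$velocity, x$jitter_rate))
  invisible(x)
}

polyline_length <- function(poly) {
  sum(sqrt(rowSums((poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE])^2)))
}

# Project points (n x 2) onto a polyline; returns per-point perpendicular
# distance and arc-length position (um, local to the polyline).
project_onto_polyline <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  nseg <- nrow(poly) - 1
  seg0 <- poly[-nrow(poly), , drop = FALSE]
  dvec <- poly[-1, , drop = FALSE] - seg0
  seglen <- sqrt(rowSums(dvec^2))
  cum0 <- c(0, cumsum(seglen))[seq_len(nseg)]
  best_d <- rep(Inf, nrow(pts)); best_arc <- numeric(nrow(pts))
  for (s in seq_len(nseg)) {
    if (seglen[s] == 0) next
    rel <- sweep(pts, 2, seg0[s, ])
    t <- pmin(pmax(as.vector(rel %*% dvec[s, ]) / seglen[s]^2, 0), 1)
    proj <- cbind(seg0[s, 1] + t * dvec[s, 1], seg0[s, 2] + t * dvec[s, 2])
    d <- sqrt(rowSums((pts - proj)^2))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_arc[upd] <- cum0[s] + t[upd] * seglen[s]
  }
  if (nrow(pts) == 1) list(dist = best_d, arc = best_arc)
  else list(dist = best_d, arc = best_arc)
}

# total arc distance (um) from the AIS to local position `arc_um` on branch b
arbor_total_distance <- function(arbor, b, arc_um) {
  d <- arc_um
  while (arbor$parent[b] != 0L) {
    d <- d + arbor$d_attach_local[b]
    b <- arbor$parent[b]
  }
  d
}

#' Map an arbor onto electrodes and assign peak amplitudes
#'
#' Each electrode within `pickup_radius` of a branch polyline records the
#' waveform of its nearest path point (no volume-conductor physics): the
#' layout row stores the branch, the axial (arc-length) distance from the
#' AIS in mm, and the electrode's peak amplitude in multiples of the noise
#' standard deviation. Axonal amplitudes are drawn uniformly from
#' `amplitude_range`; the electrode nearest the AIS receives `ais_factor`
#' times the median axonal amplitude, reflecting the ~10x larger signals at
#' the axon initial segment. `spacing_um` optionally thins electrodes along
#' each branch so that kept electrodes are at least that far apart in axial
#' distance (emulating selection of well-separated high-SNR electrodes).
#'
#' @param arbor An [arbor_model()].
#' @param array An [build_array()] electrode array.
#' @param pickup_radius Pickup radius in um (default one pitch).
#' @param spacing_um Optional minimum axial spacing between kept electrodes.
#' @param amplitude_range Range (sigma multiples) of axonal peak amplitudes.
#' @param ais_factor AIS amplitude as a multiple of the median axonal one.
#' @param seed Seed for the amplitude draw.
#' @return An `arbor_layout` data frame (electrode, x, y, branch, d_mm,
#'   offset_um, amplitude) with the walk tree and AIS electrode as
#'   attributes.
#' @export
place_arbor <- function(arbor, array, pickup_radius = NULL, spacing_um = NULL,
                        amplitude_range = c(3, 10), ais_factor = 10,
                        seed = NULL) {
  pitch <- array_pitch(array)
  pickup_radius <- pickup_radius %||% pitch
  pts <- cbind(array$x, array$y)
  nb <- length(arbor$branches)
  dist_m <- arc_m <- matrix(Inf, nrow(array), nb)
  for (b in seq_len(nb)) {
    pr <- project_onto_polyline(pts, arbor$branches[[b]])
    dist_m[, b] <- pr$dist
    arc_m[, b] <- pr$arc
  }
  branch <- max.col(-dist_m, ties.method = "first")
  offs <- dist_m[cbind(seq_len(nrow(array)), branch)]
  keep <- offs <= pickup_radius
  if (!any(keep)) stop("no electrode lies within pickup range of the arbor",
                       call. = FALSE)
  arc <- arc_m[cbind(seq_len(nrow(array)), branch)]
  d_um <- vapply(which(keep), function(i)
    arbor_total_distance(arbor, branch[i], arc[i]), 0)
  lay <- data.frame(electrode = array$electrode[keep],
                    x = array$x[keep], y = array$y[keep],
                    branch = branch[keep], d_mm = d_um / 1000,
                    offset_um = offs[keep])
  lay <- lay[order(lay$branch, lay$d_mm, lay$electrode), ]
  ais_el <- nearest_electrode(array, arbor$ais_xy)
  if (!ais_el %in% lay$electrode) {
    exy <- electrode_xy(array, ais_el)
    lay <- rbind(data.frame(electrode = ais_el, x = exy[1], y = exy[2],
                            branch = 1L, d_mm = 0, offset_um = NA_real_), lay)
  }
  if (!is.null(spacing_um)) {
    keep_rows <- logical(nrow(lay))
    for (b in unique(lay$branch)) {
      rows <- which(lay$branch == b)
      last <- -Inf
      for (r in rows) {
        if (lay$electrode[r] == ais_el || lay$d_mm[r] * 1000 >= last + spacing_um) {
          keep_rows[r] <- TRUE
          last <- lay$d_mm[r] * 1000
        }
      }
    }
    lay <- lay[keep_rows, ]
  }
  rownames(lay) <- NULL
  n_ax <- sum(lay$electrode != ais_el)
  amp_ax <- with_seed(seed, stats::runif(n_ax, amplitude_range[1], amplitude_range[2]))
  lay$amplitude <- NA_real_
  lay$amplitude[lay$electrode != ais_el] <- amp_ax
  lay$amplitude[lay$electrode == ais_el] <- ais_factor * median(amp_ax)
  structure(lay,
            arbor = arbor, pitch = pitch, ais_electrode = ais_el,
            tree = build_walk_tree(arbor, lay),
            class = c("arbor_layout", "data.frame"))
}

# Node network for the jitter walk: per branch, sorted axial node positions
# (attachment point + electrode projections + child attachment points), with
# the mapping from layout rows to (branch, node).
build_walk_tree <- function(arbor, lay) {
  nb <- length(arbor$branches)
  d_attach_total <- vapply(seq_len(nb), function(b)
    if (b == 1) 0 else arbor_total_distance(arbor, arbor$parent[b],
                                            arbor$d_attach_local[b]), 0) / 1000
  nodes <- vector("list", nb)
  for (b in seq_len(nb)) {
    dv <- lay$d_mm[lay$branch == b]
    child_at <- d_attach_total[which(arbor$parent == b)]
    nodes[[b]] <- sort(unique(c(d_attach_total[b], dv, child_at)))
  }
  el_branch <- lay$branch
  el_node <- vapply(seq_len(nrow(lay)), function(i)
    which.min(abs(nodes[[el_branch[i]]] - lay$d_mm[i])), 0L)
  attach_node <- vapply(seq_len(nb), function(b) {
    if (b == 1) return(1L)
    which.min(abs(nodes[[arbor$parent[b]]] - d_attach_total[b]))
  }, 0L)
  list(n_branches = nb, parent = arbor$parent, d_nodes = nodes,
       attach_node = attach_node, el_branch = el_branch, el_node = el_node)
}

#' Bundled simulation presets
#'
#' Ready-made array + arbor geometries used throughout the package:
#' \describe{
#' \item{`"detection"`}{a ~500 um two-branch arbor on a 24 x 24 grid
#'   (17.8 um pitch); every electrode within one pitch of the path records
#'   the AP, giving ~55 axonal electrodes. Used for the mixed-trial
#'   detection benchmark.}
#' \item{`"recovery"`}{a straight 1.5 mm axon with 13 electrodes kept at
#'   ~125 um axial spacing; used for velocity and jitter-rate recovery.}
#' \item{`"stimulation"`}{a 500 um axon with recording electrodes at
#'   ~150 um spacing, for voltage-sweep latency/jitter experiments.}
#' }
#'
#' @param preset Preset name.
#' @param seed Seed for the amplitude draw.
#' @param velocity,jitter_rate Propagation parameters passed to the arbor.
#' @return List with elements `array`, `arbor`, `layout`.
#' @export
arbor_preset <- function(preset = c("detection", "recovery", "stimulation"),
                         seed = 1, velocity = NULL, jitter_rate = NULL) {
  preset <- match.arg(preset)
  p <- 17.8
  if (preset == "detection") {
    array <- build_array(24, 24, p)
    ais <- c(3.5 * p, 16.5 * p)
    branches <- list(
      rbind(ais, c(15.5 * p, 16.5 * p), c(15.5 * p, 6.5 * p)),
      rbind(c(10.5 * p, 16.5 * p), c(10.5 * p, 10.5 * p))
    )
    arbor <- arbor_model(ais, branches, velocity = velocity %||% 0.7,
                         jitter_rate = jitter_rate %||% 100)
    layout <- place_arbor(arbor, array, seed = seed)
  } else if (preset == "recovery") {
    array <- build_array(3, 88, p)
    ais <- c(0.25 * p, p)
    arbor <- arbor_model(ais, list(rbind(ais, c(85.25 * p, p))),
                         velocity = velocity %||% 0.71,
                         jitter_rate = jitter_rate %||% 100)
    layout <- place_arbor(arbor, array, spacing_um = 120, seed = seed)
  } else {
    array <- build_array(3, 30, p)
    ais <- c(0.25 * p, p)
    arbor <- arbor_model(ais, list(rbind(ais, c(28.25 * p, p))),
                         velocity = velocity %||% 0.7,
                         jitter_rate = jitter_rate %||% 100)
    layout <- place_arbor(arbor, array, spacing_um = 150, seed = seed)
  }
  list(array = array, arbor = arbor, layout = layout)
}
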