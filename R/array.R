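#' Build a regular grid of recording electrodes
#'
#' Constructs a planar electrode array with row-major electrode indexing:
#' electrode 1 sits at the origin, ids then run along the first row.
#' The default center-to-center pitch of 17.8 um matches CMOS high-density
#' arrays with ~3150 electrodes/mm^2.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param pitch Center-to-center electrode spacing in micrometres.
#' @return An `electrode_array`: a data frame with columns `electrode`, `x`,
#'   `y` (um) and a `pitch` attribute.
#' @examples
#' arr <- build_array(2, 2)
#' arr$x  # 0, 17.8, 0, 17.8
#' @export
build_array <- function(n_rows, n_cols, pitch = 17.8) {
  if (!is.numeric(pitch) || length(pitch) != 1 || !is.finite(pitch) || pitch <= 0)
    stop("`pitch` must be a single positive number (micrometres)", call. = FALSE)
  if (n_rows < 1 || n_cols < 1)
    stop("`n_rows` and `n_cols` must be >= 1", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  grid <- expand.grid(cx = seq_len(n_cols) - 1L, cy = seq_len(n_rows) - 1L)
  arr <- data.frame(
    electrode = seq_len(nrow(grid)),
    x = grid$cx * pitch,
    y = grid$cy * pitch
  )
  structure(arr, pitch = pitch, class = c("electrode_array", "data.frame"))
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d electrodes, pitch %.4g um, extent %.3g x %.3g um\n",
              nrow(x), attr(x, "pitch"), max(x$x) - min(x$x), max(x$y) - min(x$y)))
  invisible(x)
}

array_pitch <- function(array) attr(array, "pitch") %||% 17.8

# positions of the given electrode ids as an n x 2 matrix
electrode_xy <- function(array, ids) {
  idx <- match(ids, array$electrode)
  if (anyNA(idx)) stop("unknown electrode id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  cbind(array$x[idx], array$y[idx])
}

# id of the electrode nearest to a point (x, y); ties -> lowest id
nearest_electrode <- function(array, xy) {
  d2 <- (array$x - xy[1])^2 + (array$y - xy[2])^2
  array$electrode[which.min(d2)]
}
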