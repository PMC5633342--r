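#' Multichannel extracellular recording container
#'
#' In-memory representation of a (possibly simulated) HD-MEA recording:
#' a dense `electrodes x samples` voltage matrix in uV, the sampling rate,
#' an electrode table with array coordinates, an optional stimulation table
#' and free-form metadata. Sample `i` corresponds to time `(i - 1)/fs`.
#'
#' @param traces Numeric matrix, electrodes x samples (uV).
#' @param fs Sampling rate in Hz.
#' @param electrodes Data frame with columns `electrode`, `x`, `y` (um);
#'   rows must match the rows of `traces`.
#' @param stim Optional data frame (`trial`, `time_s`, `voltage_mV`, and
#'   optionally `episode`, `pulse_index`).
#' @param meta Named list of metadata (seed, generator parameters, ...).
#' @return An object of class `recording`.
#' @export
recording <- function(traces, fs, electrodes, stim = NULL, meta = list()) {
  traces <- as.matrix(traces)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive sampling rate (Hz)", call. = FALSE)
  if (!all(c("electrode", "x", "y") %in% names(electrodes)))
    stop("`electrodes` must have columns electrode, x, y", call. = FALSE)
  if (nrow(electrodes) != nrow(traces))
    stop(sprintf("electrode table (%d rows) does not match traces (%d rows)",
                 nrow(electrodes), nrow(traces)), call. = FALSE)
  if (!is.null(stim) && nrow(stim) > 0 &&
      any(stim$time_s < 0 | stim$time_s > ncol(traces) / fs))
    stop("stimulation times fall outside the trace duration", call. = FALSE)
  structure(list(traces = traces, fs = fs,
                 electrodes = as.data.frame(electrodes),
                 stim = stim, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d electrodes x %d samples (%.3g s at %g kHz)\n",
              nrow(x$traces), ncol(x$traces), ncol(x$traces) / x$fs,
              x$fs / 1000))
  invisible(x)
}

# trace rows for given electrode ids
rec_rows <- function(rec, ids) {
  idx <- match(ids, rec$electrodes$electrode)
  if (anyNA(idx)) stop("electrode(s) not present in recording: ",
                       paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

REC_SCHEMA_VERSION <- "1"

#' Write / read the recording container
#'
#' The on-disk container is a directory holding `meta.json` (sampling rate,
#' schema version, metadata), `electrodes.csv`, `traces.feather` (float64
#' Arrow/Feather, one column per electrode, bit-exact round trip) and, when
#' present, `stimulation.csv`. The write -> read round trip preserves traces
#' bit-exactly and metadata field-for-field.
#'
#' @param rec A [recording()].
#' @param path Container directory (created if missing).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = REC_SCHEMA_VERSION, fs = rec$fs,
               n_electrodes = nrow(rec$traces), n_samples = ncol(rec$traces),
               meta = rec$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(rec$electrodes, file.path(path, "electrodes.csv"),
            row.names = FALSE)
  tr <- as.data.frame(t(rec$traces))
  names(tr) <- paste0("e", rec$electrodes$electrode)
  arrow::write_feather(tr, file.path(path, "traces.feather"))
  if (!is.null(rec$stim))
    write.csv(rec$stim, file.path(path, "stimulation.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop(sprintf("container at '%s' is missing '%s'",
                                       path, f), call. = FALSE)
    fp
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != REC_SCHEMA_VERSION)
    stop(sprintf("unrecognized container schema version '%s' (expected '%s')",
                 meta$schema_version %||% "<none>", REC_SCHEMA_VERSION),
         call. = FALSE)
  for (f in c("fs", "n_electrodes", "n_samples"))
    if (is.null(meta[[f]])) stop("meta.json is missing field '", f, "'",
                                 call. = FALSE)
  el <- read.csv(need("electrodes.csv"))
  tr <- as.data.frame(arrow::read_feather(need("traces.feather")))
  traces <- t(as.matrix(tr))
  dimnames(traces) <- NULL
  if (nrow(traces) != meta$n_electrodes || ncol(traces) != meta$n_samples)
    stop("trace dataset does not match the dimensions declared in meta.json",
         call. = FALSE)
  stim <- NULL
  if (file.exists(file.path(path, "stimulation.csv")))
    stim <- read.csv(file.path(path, "stimulation.csv"))
  m <- meta$meta
  recording(traces, meta$fs, el, stim = stim,
            meta = if (is.null(m)) list() else as.list(m))
}

#' Write / read a ground-truth table
#'
#' Plain CSV with one row per (trial, electrode) ground-truth arrival.
#'
#' @param truth Data frame as produced by the simulators.
#' @param path CSV file path.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) read.csv(path)
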