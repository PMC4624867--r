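#' Labeled multichannel EEG recording
#'
#' The unit of all signal processing in plinet: a channels x samples numeric
#' matrix together with unique channel labels, a sampling rate, and an
#' ordered provenance of the processing steps already applied.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param channel_labels character vector of unique montage names, one per
#'   row of `data`. If `data` has rownames and `channel_labels` is missing,
#'   the rownames are used.
#' @param fs_hz sampling rate in Hz (positive scalar).
#' @param provenance character vector of processing steps already applied
#'   (usually empty for a fresh recording).
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `data`, `channel_labels`, `fs_hz`, `provenance`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), 2, 250),
#'                      c("C3", "C4"), fs_hz = 250)
#' rec
#' @export
eeg_recording <- function(data, channel_labels = rownames(data), fs_hz,
                          provenance = character()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    stop("channel labels are required (argument or rownames)", call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("length(channel_labels) must equal nrow(data)", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("`fs_hz` must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, channel_labels = channel_labels,
         fs_hz = as.numeric(fs_hz), provenance = as.character(provenance)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = " "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname eeg_recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs_hz

# internal: return a copy with new data and one provenance step appended
with_step <- function(rec, data, step, fs_hz = rec$fs_hz) {
  eeg_recording(data, rec$channel_labels, fs_hz,
                provenance = c(rec$provenance, step))
}

stopifnot_channels <- function(rec, labels) {
  missing <- setdiff(labels, rec$channel_labels)
  if (length(missing)) {
    stop("unknown channel label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}
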