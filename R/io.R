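#' Read a recording from EDF or delimited text
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"`.
#' @param fs_hz sampling rate in Hz; required for delimited files (EDF
#'   carries its own).
#' @param transpose for delimited files: `FALSE` (default) means one
#'   channel per row after a header row of channel labels; `TRUE` means
#'   one channel per column (samples down the rows).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("edf", "delimited"),
                           fs_hz = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") read_edf(path)
  else read_delimited_recording(path, fs_hz = fs_hz, transpose = transpose)
}

#' Delimited-text recording I/O
#'
#' Tab-separated interchange format: the first row holds the channel
#' labels; each following row holds one channel's samples (or, with
#' `transpose = TRUE`, one sample per row with channels across columns).
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @param fs_hz sampling rate of the stored data (reader only).
#' @param transpose store/read samples down the rows instead of across.
#' @return The recording (reader) or `path` invisibly (writer).
#' @export
write_delimited_recording <- function(rec, path, transpose = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  m <- if (transpose) t(rec$data) else rec$data
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_delimited_recording
#' @export
read_delimited_recording <- function(path, fs_hz, transpose = FALSE) {
  if (is.null(fs_hz)) {
    stop("`fs_hz` is required for delimited recordings", call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed delimited recording: ", path,
                              " (need header + data rows)", call. = FALSE)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  body <- lapply(seq(2, length(lines)), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "\t",
                                              fixed = TRUE)[[1]]))
    if (anyNA(v)) stop("non-numeric value at line ", i, " of ", path,
                       call. = FALSE)
    v
  })
  if (length(unique(lengths(body))) != 1) {
    stop("ragged rows in ", path, call. = FALSE)
  }
  m <- do.call(rbind, body)
  if (transpose) m <- t(m)
  if (nrow(m) != length(labels)) {
    stop("label count (", length(labels), ") does not match channel rows (",
         nrow(m), ") in ", path, call. = FALSE)
  }
  eeg_recording(m, labels, fs_hz, provenance = paste0("read(", path, ")"))
}

# ---- minimal EDF (European Data Format, 16-bit) support -------------------

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' EDF recording I/O
#'
#' Writes and reads plain (continuous) EDF: 16-bit samples, one data
#' record per second. The sampling rate must therefore be a whole number
#' of samples per second, and a trailing partial second is dropped on
#' write. Physical scaling is per channel (full range of the data), so
#' round-trip error is bounded by the channel's range divided by 2^16.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @param physical_dim physical dimension label stored per channel.
#' @return The recording (reader) or `path` invisibly (writer).
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  ns <- n_channels(rec)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)",
                      call. = FALSE)
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("plinet", 80), edf_field("simulated", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 + ns * 256, 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(1, 8), edf_field(ns, 4)
  )
  sig <- paste0(
    paste(edf_field(rec$channel_labels, 16), collapse = ""),
    paste(edf_field(rep("", ns), 80), collapse = ""),
    paste(edf_field(rep(physical_dim, ns), 8), collapse = ""),
    paste(edf_field(formatC(pmin_, format = "g", digits = 7), 8),
          collapse = ""),
    paste(edf_field(formatC(pmax_, format = "g", digits = 7), 8),
          collapse = ""),
    paste(edf_field(rep(dmin, ns), 8), collapse = ""),
    paste(edf_field(rep(dmax, ns), 8), collapse = ""),
    paste(edf_field(rep("", ns), 80), collapse = ""),
    paste(edf_field(rep(fs, ns), 8), collapse = ""),
    paste(edf_field(rep("", ns), 32), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)

  # re-read the headers' ASCII physical limits so scaling matches readers
  pmin_h <- as.numeric(edf_field(formatC(pmin_, format = "g", digits = 7), 8))
  pmax_h <- as.numeric(edf_field(formatC(pmax_, format = "g", digits = 7), 8))
  scale <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((data[i, cols] - pmin_h[i]) * scale[i]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) {
    stop("malformed EDF: truncated header in ", path, call. = FALSE)
  }
  fld <- function(s, from, width) substr(s, from, from + width - 1)
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) {
    stop("malformed EDF header in ", path, call. = FALSE)
  }
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  take <- function(offset, width) {
    start <- offset * ns
    vapply(seq_len(ns) - 1L,
           function(i) trimws(substr(sig, start + i * width + 1,
                                     start + (i + 1) * width)),
           character(1))
  }
  # field-major blocks: label 16, transducer 80, physical dim 8,
  # physical min/max 8+8, digital min/max 8+8, prefilter 80, spr 8
  labels <- take(0, 16)
  pmin_ <- as.numeric(take(104, 8))
  pmax_ <- as.numeric(take(112, 8))
  dmin <- as.numeric(take(120, 8))
  dmax <- as.numeric(take(128, 8))
  spr <- as.integer(take(216, 8))
  if (length(unique(spr)) != 1) {
    stop("EDF with per-channel sampling rates is not supported",
         call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels in EDF: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[1]) {
        stop("malformed EDF: truncated data record ", r, " in ", path,
             call. = FALSE)
      }
      cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      data[i, cols] <- (dig - dmin[i]) * scale[i] + pmin_[i]
    }
  }
  eeg_recording(data, labels, fs, provenance = paste0("read(", path, ")"))
}

# ---- connectivity matrix / table serialization ---------------------------

#' Connectivity matrix I/O
#'
#' TSV form: square matrix with channel labels as header row and first
#' column. JSON form: object with `band`, `labels`, `weights`. Both
#' round-trip losslessly.
#'
#' @param m a `pli_matrix`.
#' @param path file path.
#' @return The matrix (readers) or `path` invisibly (writers).
#' @export
write_pli_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(unclass(m)), path, sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_pli_matrix_tsv
#' @export
read_pli_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  pli_matrix(as.matrix(df))
}

#' @rdname write_pli_matrix_tsv
#' @export
write_pli_matrix_json <- function(m, path) {
  jsonlite::write_json(
    list(band = attr(m, "band"), labels = rownames(m),
         weights = unclass(m)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_pli_matrix_tsv
#' @export
read_pli_matrix_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  dimnames(w) <- list(obj$labels, obj$labels)
  pli_matrix(w, band = obj$band)
}

#' Cohort manifest I/O
#'
#' TSV with columns `subject_id`, `group`, `score`.
#'
#' @param manifest manifest tibble.
#' @param path file path.
#' @return The manifest (reader) or `path` invisibly (writer).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric"))
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject ids in manifest", call. = FALSE)
  }
  tibble::as_tibble(df)
}
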