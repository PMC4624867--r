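#' Re-reference to the average of two channels
#'
#' Subtracts the sample-wise mean of two reference channels (typically the
#' left and right mastoids) from every channel.
#'
#' @param rec an [eeg_recording()].
#' @param ref_labels character vector of exactly two channel labels.
#' @return The re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, ref_labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(ref_labels) != 2L) {
    stop("`ref_labels` must name exactly two channels", call. = FALSE)
  }
  stopifnot_channels(rec, ref_labels)
  ref <- colMeans(rec$data[ref_labels, , drop = FALSE])
  with_step(rec, sweep(rec$data, 2, ref, "-"),
            sprintf("rereference(%s)", paste(ref_labels, collapse = ",")))
}

# RBJ-cookbook 2nd-order IIR notch; returns list(b, a)
design_notch <- function(freq_hz, fs_hz, q = 30) {
  w0 <- 2 * pi * freq_hz / fs_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch filter (line-noise rejection)
#'
#' Zero-phase narrowband rejection at `freq_hz`, implemented as a
#' 2nd-order IIR notch (quality factor 30) applied forward and backward.
#'
#' @param rec an [eeg_recording()].
#' @param freq_hz notch center frequency in Hz (default 50, the line
#'   frequency the analysis chain targets); must be below Nyquist.
#' @return The filtered [eeg_recording()].
#' @export
notch <- function(rec, freq_hz = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (freq_hz >= rec$fs_hz / 2) {
    stop("notch frequency ", freq_hz, " Hz is at or above Nyquist (",
         rec$fs_hz / 2, " Hz)", call. = FALSE)
  }
  f <- design_notch(freq_hz, rec$fs_hz)
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(f$b, f$a, x)))
  with_step(rec, out, sprintf("notch(%g Hz)", freq_hz))
}

#' Downsample with anti-alias filtering
#'
#' Reduces the sampling rate to `target_fs`. Integer decimation factors use
#' a zero-phase 8th-order Butterworth anti-alias low-pass (cutoff 80% of
#' the new Nyquist) followed by sample picking; non-integer ratios use
#' polyphase resampling. Upsampling is refused.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate in Hz (<= current rate).
#' @return The downsampled [eeg_recording()] with `fs_hz = target_fs`.
#' @export
downsample <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs_hz) {
    stop("target_fs (", target_fs, ") exceeds current rate (", rec$fs_hz,
         "); upsampling is not supported", call. = FALSE)
  }
  if (target_fs == rec$fs_hz) {
    return(with_step(rec, rec$data, sprintf("downsample(%g Hz)", target_fs)))
  }
  ratio <- rec$fs_hz / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    bw <- signal::butter(8, 0.8 / q, type = "low")
    out <- t(apply(rec$data, 1, function(x) {
      signal::filtfilt(bw, x)[seq(1, length(x), by = q)]
    }))
  } else {
    frac <- as.integer(c(target_fs, rec$fs_hz) /
                         gcd_int(target_fs, rec$fs_hz))
    n_out <- floor(ncol(rec$data) * target_fs / rec$fs_hz)
    out <- t(apply(rec$data, 1, function(x) {
      signal::resample(x, frac[1], frac[2])[seq_len(n_out)]
    }))
  }
  with_step(rec, out, sprintf("downsample(%g Hz)", target_fs),
            fs_hz = target_fs)
}

gcd_int <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Band-pass filter into an analysis band
#'
#' Zero-phase band-pass with the squared-magnitude response of a
#' 4th-order Butterworth (the response a forward-backward application
#' yields), realized as a frequency-domain multiply. This keeps the
#' operation exactly phase-free and numerically benign even for narrow
#' low-frequency bands, where a time-domain 8-pole recursion is
#' ill-conditioned — phase preservation matters because phase differences
#' are the quantity the connectivity stage measures.
#'
#' @param rec an [eeg_recording()].
#' @param band a [band_definition()] or shipped band name.
#' @param order Butterworth prototype order (default 4).
#' @return The band-limited [eeg_recording()].
#' @export
bandpass <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- as_band(band)
  if (band$high_hz >= rec$fs_hz / 2) {
    stop("band '", band$name, "' upper edge ", band$high_hz,
         " Hz is at or above Nyquist (", rec$fs_hz / 2, " Hz)",
         call. = FALSE)
  }
  n <- ncol(rec$data)
  f <- (seq_len(n) - 1) / n * rec$fs_hz
  f <- pmin(f, rec$fs_hz - f)       # two-sided spectrum frequencies
  # |H|^2 of an order-`order` Butterworth band-pass (analog prototype):
  # 1 / (1 + Q^(2*order)), Q = (f^2 - f_lo*f_hi) / (f * (f_hi - f_lo))
  q <- ifelse(f > 0,
              (f^2 - band$low_hz * band$high_hz) /
                (f * (band$high_hz - band$low_hz)),
              Inf)
  h2 <- 1 / (1 + q^(2 * order))
  h2[!is.finite(q)] <- 0
  out <- t(apply(rec$data, 1, function(x) {
    Re(stats::fft(stats::fft(x) * h2, inverse = TRUE)) / n
  }))
  with_step(rec, out, sprintf("bandpass(%s %g-%g Hz)", band$name,
                              band$low_hz, band$high_hz))
}

#' Extract a fixed-length analysis segment
#'
#' Returns the first contiguous window of `length_s` seconds. When
#' `reject_threshold` is set, windows containing any sample with absolute
#' amplitude above the threshold are skipped (the search restarts just
#' after the offending sample) until a clean window is found.
#'
#' @param rec an [eeg_recording()].
#' @param length_s segment length in seconds (default 180, a 3-minute
#'   resting-state epoch).
#' @param reject_threshold optional absolute-amplitude rejection threshold
#'   (same units as the data); `NULL` disables rejection.
#' @return The extracted [eeg_recording()].
#' @export
extract_segment <- function(rec, length_s = 180, reject_threshold = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- as.integer(round(length_s * rec$fs_hz))
  total <- ncol(rec$data)
  if (n > total) {
    stop("recording (", total / rec$fs_hz, " s) shorter than requested ",
         "segment (", length_s, " s)", call. = FALSE)
  }
  start <- 1L
  if (!is.null(reject_threshold)) {
    bad <- which(apply(abs(rec$data) > reject_threshold, 2, any))
    repeat {
      if (start + n - 1L > total) {
        gaps <- diff(c(0L, bad, total + 1L)) - 1L
        stop("no clean window of ", length_s, " s below threshold ",
             reject_threshold, "; longest clean stretch is ",
             max(gaps) / rec$fs_hz, " s", call. = FALSE)
      }
      hit <- bad[bad >= start & bad <= start + n - 1L]
      if (!length(hit)) break
      start <- max(hit) + 1L
    }
  }
  with_step(rec, rec$data[, start:(start + n - 1L), drop = FALSE],
            sprintf("segment(%gs @ %.3fs)", length_s,
                    (start - 1L) / rec$fs_hz))
}
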