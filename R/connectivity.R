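#' Instantaneous phase via the analytic signal
#'
#' Computes the phase of the analytic signal (FFT realization of the
#' Hilbert transform) of a band-limited series, in `(-pi, pi]` per sample.
#' When `fs_hz` is supplied, one second at each end is flagged invalid
#' (attribute `"valid"`) so filter and analytic-signal edge transients can
#' be excluded downstream.
#'
#' @param x numeric vector, a single band-limited channel.
#' @param fs_hz optional sampling rate, used only to flag edge samples.
#' @param edge_s seconds flagged invalid at each end (default 1).
#' @return Numeric vector of phases with attribute `valid` (logical) when
#'   `fs_hz` is given.
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' ph <- instantaneous_phase(cos(2 * pi * 10 * t), fs_hz = 250)
#' @export
instantaneous_phase <- function(x, fs_hz = NULL, edge_s = 1) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("constant (zero-variance) input has no defined phase",
         call. = FALSE)
  }
  ph <- Arg(analytic_signal(x))
  ph[ph == -pi] <- pi
  if (!is.null(fs_hz)) {
    edge <- min(as.integer(round(edge_s * fs_hz)), floor(length(x) / 2))
    valid <- rep(TRUE, length(x))
    if (edge > 0) {
      valid[seq_len(edge)] <- FALSE
      valid[seq(length(x) - edge + 1L, length(x))] <- FALSE
    }
    attr(ph, "valid") <- valid
  }
  ph
}

# analytic signal by zeroing negative frequencies of the FFT
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Phase lag index of a phase-difference series
#'
#' The PLI is the absolute mean of the sign of the (wrapped) phase
#' differences, `|<sign(delta_phi)>|`: it measures the asymmetry of the
#' phase-difference distribution. It is 0 when phase differences center on
#' 0 mod pi (no coupling, or zero-lag coupling such as volume conduction)
#' and 1 for perfect locking at a nonzero lag. Samples whose wrapped
#' difference is exactly 0 or pi contribute 0 to the mean.
#'
#' @param delta_phi numeric vector of phase differences (radians; wrapped
#'   internally).
#' @param valid_mask optional logical inclusion mask (e.g. the `valid`
#'   attribute from [instantaneous_phase()]).
#' @return Scalar in `[0, 1]`.
#' @examples
#' pli(rep(pi / 2, 1000))        # perfect nonzero-lag locking -> 1
#' pli(rep(0, 1000))             # zero-lag -> 0
#' @export
pli <- function(delta_phi, valid_mask = NULL) {
  if (!is.null(valid_mask)) {
    stopifnot(length(valid_mask) == length(delta_phi))
    delta_phi <- delta_phi[valid_mask]
  }
  if (!length(delta_phi)) {
    stop("no valid samples left after masking", call. = FALSE)
  }
  w <- wrap_phase(delta_phi)
  s <- sign(w)
  s[w == pi] <- 0     # 0 mod pi contributes nothing to the asymmetry
  abs(mean(s))
}

#' Band-wise PLI connectivity matrix
#'
#' Band-pass filters the recording, extracts each channel's instantaneous
#' phase, and computes the PLI for every unordered channel pair, excluding
#' one second of edge samples at each end. The result is a symmetric
#' N x N matrix with zero diagonal and entries in `[0, 1]`.
#'
#' @param rec an [eeg_recording()], already segmented.
#' @param band a [band_definition()] or shipped band name.
#' @param edge_s seconds discarded at each end of the phase series.
#' @return A numeric matrix with class `pli_matrix`, channel labels as
#'   dimnames and the band name in attribute `band`.
#' @export
connectivity_matrix <- function(rec, band, edge_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- as_band(band)
  filt <- bandpass(rec, band)
  nc <- n_channels(rec)
  ph <- matrix(0, nc, ncol(filt$data))
  for (i in seq_len(nc)) {
    ph[i, ] <- instantaneous_phase(filt$data[i, ])
  }
  edge <- min(as.integer(round(edge_s * rec$fs_hz)), floor(ncol(ph) / 2))
  keep <- seq_len(ncol(ph))
  if (edge > 0) keep <- keep[-c(seq_len(edge),
                                seq(ncol(ph) - edge + 1L, ncol(ph)))]
  # sign(sin(phi_i - phi_j)) via the sine difference identity, vectorized
  s <- sin(ph[, keep, drop = FALSE])
  co <- cos(ph[, keep, drop = FALSE])
  w <- matrix(0, nc, nc, dimnames = list(rec$channel_labels,
                                         rec$channel_labels))
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      w[i, j] <- w[j, i] <-
        abs(mean(sign(s[i, ] * co[j, ] - co[i, ] * s[j, ])))
    }
  }
  pli_matrix(w, band$name)
}

#' Construct / validate a PLI matrix object
#'
#' @param w symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, and channel labels as dimnames.
#' @param band band name string.
#' @return `w` with class `pli_matrix` and attribute `band`.
#' @export
pli_matrix <- function(w, band = NA_character_) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (is.null(rownames(w))) stop("matrix needs channel labels", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-12) stop("matrix must be symmetric", call. = FALSE)
  if (any(diag(w) != 0)) stop("diagonal must be exactly 0", call. = FALSE)
  if (any(w < 0 | w > 1)) stop("entries must lie in [0, 1]", call. = FALSE)
  structure(w, band = band, class = c("pli_matrix", class(w)))
}

#' Global mean PLI
#'
#' Arithmetic mean of the `N(N-1)/2` upper-triangle entries (diagonal
#' excluded) of a connectivity matrix.
#'
#' @param m a `pli_matrix` (or any symmetric weight matrix).
#' @return Scalar in `[0, 1]`.
#' @export
global_mean_pli <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 channels", call. = FALSE)
  mean(m[upper.tri(m)])
}

#' Region-grouped short/long-distance PLI summary
#'
#' Averages connectivity over channel-pair groups defined by a region map:
#' 8 short-distance values (pairs within one region of one hemisphere),
#' 12 long-distance intra-hemispheric values (pairs spanning two different
#' regions of the same hemisphere), 4 long-distance interhemispheric
#' values (pairs spanning homolog regions of the two hemispheres), plus
#' the global mean. Midline channels contribute to the global mean only;
#' non-homolog cross-hemisphere pairs belong to no group. Groups with no
#' pairs yield `NA`.
#'
#' @param m a `pli_matrix`.
#' @param map region map tibble (see [region_map()]); every matrix label
#'   must appear in it.
#' @return A tibble with columns `measure` (e.g.
#'   `short_left_frontal`, `long_intra_left_frontal_temporal`,
#'   `long_inter_frontal`, `global_mean`), `type`, and `value`.
#' @export
distance_summary <- function(m, map = region_map(rownames(m))) {
  validate_region_map(map)
  labels <- rownames(m)
  missing <- setdiff(labels, map$channel)
  if (length(missing)) {
    stop("matrix channels absent from region map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  map <- map[match(labels, map$channel), ]
  regions <- c("frontal", "central", "temporal", "occipital")
  hemis <- c("left", "right")
  region_pairs <- utils::combn(regions, 2, simplify = FALSE)

  rows <- list()
  add <- function(measure, type, idx_a, idx_b) {
    # mean over all pairs (one from idx_a, one from idx_b); for the
    # within-group case idx_a == idx_b and distinct pairs are used
    if (identical(idx_a, idx_b)) {
      val <- if (length(idx_a) >= 2) {
        sub <- m[idx_a, idx_a, drop = FALSE]
        mean(sub[upper.tri(sub)])
      } else NA_real_
    } else {
      val <- if (length(idx_a) && length(idx_b)) {
        mean(m[idx_a, idx_b, drop = FALSE])
      } else NA_real_
    }
    rows[[length(rows) + 1L]] <<-
      tibble::tibble(measure = measure, type = type, value = val)
  }

  for (h in hemis) for (r in regions) {
    idx <- which(map$hemisphere == h & map$region == r)
    add(paste("short", h, r, sep = "_"), "short", idx, idx)
  }
  for (h in hemis) for (rp in region_pairs) {
    i1 <- which(map$hemisphere == h & map$region == rp[1])
    i2 <- which(map$hemisphere == h & map$region == rp[2])
    add(paste("long_intra", h, rp[1], rp[2], sep = "_"), "long_intra",
        i1, i2)
  }
  for (r in regions) {
    il <- which(map$hemisphere == "left" & map$region == r)
    ir <- which(map$hemisphere == "right" & map$region == r)
    add(paste("long_inter", r, sep = "_"), "long_inter", il, ir)
  }
  rows[[length(rows) + 1L]] <-
    tibble::tibble(measure = "global_mean", type = "global",
                   value = global_mean_pli(m))
  do.call(rbind, rows)
}
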