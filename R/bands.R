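#' Canonical EEG analysis bands
#'
#' The six frequency bands used throughout the package: delta (1-4 Hz),
#' theta (4-8 Hz), lower alpha (8-10 Hz), upper alpha (10-13 Hz),
#' beta (13-30 Hz) and gamma (30-45 Hz).
#'
#' @return A tibble with columns `name`, `low_hz`, `high_hz`.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble::tibble(
    name    = c("delta", "theta", "lower_alpha", "upper_alpha", "beta", "gamma"),
    low_hz  = c(1, 4, 8, 10, 13, 30),
    high_hz = c(4, 8, 10, 13, 30, 45)
  )
}

#' Band definition
#'
#' Construct a band definition, either one of the six shipped bands by name
#' or a custom band with explicit edges.
#'
#' @param name band name; one of `eeg_bands()$name` for shipped bands, or
#'   any label when `low_hz`/`high_hz` are given.
#' @param low_hz,high_hz band edges in Hz (0 < low < high). Optional when
#'   `name` is a shipped band.
#' @return A list with class `band_definition` and fields `name`, `low_hz`,
#'   `high_hz`.
#' @examples
#' band_definition("lower_alpha")
#' band_definition("mu", 9, 11)
#' @export
band_definition <- function(name, low_hz = NULL, high_hz = NULL) {
  if (is.null(low_hz) || is.null(high_hz)) {
    bands <- eeg_bands()
    i <- match(name, bands$name)
    if (is.na(i)) {
      stop("unknown band '", name, "'; shipped bands are: ",
           paste(bands$name, collapse = ", "), call. = FALSE)
    }
    low_hz <- bands$low_hz[i]
    high_hz <- bands$high_hz[i]
  }
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) band else band_definition(band)
}

# is f strictly inside one of the six shipped bands?
in_some_band <- function(f) {
  b <- eeg_bands()
  any(f > b$low_hz & f < b$high_hz)
}
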