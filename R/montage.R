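#' Default 59-channel 10-10 montage
#'
#' The channel set used for full-scale analyses: 59 labels from the
#' international 10-10 system covering frontal, central, temporal and
#' occipito-parietal scalp in both hemispheres plus seven midline sites.
#'
#' @return Character vector of 59 channel labels.
#' @examples
#' length(default_montage())
#' @export
default_montage <- function() {
  c(
    # frontal
    "Fp1", "AF3", "AF7", "F1", "F3", "F5", "F7",
    "Fp2", "AF4", "AF8", "F2", "F4", "F6", "F8",
    # central (fronto-central and centro-parietal rows included)
    "FC1", "FC3", "FC5", "C1", "C3", "C5", "CP1", "CP3", "CP5",
    "FC2", "FC4", "FC6", "C2", "C4", "C6", "CP2", "CP4", "CP6",
    # temporal
    "FT7", "T7", "TP7", "FT8", "T8", "TP8",
    # occipital (parietal rows grouped with occipital)
    "P1", "P3", "P5", "P7", "PO3", "PO7", "O1",
    "P2", "P4", "P6", "P8", "PO4", "PO8", "O2",
    # midline
    "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz"
  )
}

#' Region map: channel to (hemisphere, region)
#'
#' Assigns each channel of a 10-10 montage to a hemisphere (`left`,
#' `right`, `midline`) and, for lateral channels, to one of four scalp
#' regions (`frontal`, `central`, `temporal`, `occipital`). Midline
#' channels (z suffix) carry no region and are excluded from all
#' region-grouped connectivity summaries.
#'
#' The assignment is by 10-10 label prefix: `Fp`/`AF`/`F` are frontal,
#' `FC`/`C`/`CP` central, `FT`/`T`/`TP` temporal, and `P`/`PO`/`O`
#' occipital; odd final digits are left-hemisphere, even right. Placing
#' the parietal row with the occipital group is an approximation that can
#' be overridden by supplying a custom map (any tibble with columns
#' `channel`, `hemisphere`, `region`).
#'
#' @param channels character vector of 10-10 channel labels
#'   (default: [default_montage()]).
#' @return A tibble with columns `channel`, `hemisphere`, `region`
#'   (`region` is `NA` for midline channels).
#' @examples
#' region_map()
#' @export
region_map <- function(channels = default_montage()) {
  if (anyDuplicated(channels)) stop("duplicate channel labels", call. = FALSE)
  parsed <- lapply(channels, parse_1010_label)
  tibble::tibble(
    channel    = as.character(channels),
    hemisphere = vapply(parsed, `[[`, "", "hemisphere"),
    region     = vapply(parsed, `[[`, "", "region")
  )
}

# classify one 10-10 label by prefix and digit parity
parse_1010_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3L) {
    stop("cannot parse 10-10 channel label '", label, "'", call. = FALSE)
  }
  prefix <- m[2]
  suffix <- m[3]
  if (identical(suffix, "z")) {
    return(list(hemisphere = "midline", region = NA_character_))
  }
  digit <- as.integer(suffix)
  hemi <- if (digit %% 2L == 1L) "left" else "right"
  region <- switch(prefix,
    Fp = , AF = , F = "frontal",
    FC = , C = , CP = "central",
    FT = , T = , TP = "temporal",
    P = , PO = , O = "occipital",
    stop("unknown 10-10 prefix '", prefix, "' in label '", label, "'",
         call. = FALSE)
  )
  list(hemisphere = hemi, region = region)
}

validate_region_map <- function(map) {
  need <- c("channel", "hemisphere", "region")
  if (!all(need %in% names(map))) {
    stop("region map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok_h <- map$hemisphere %in% c("left", "right", "midline")
  if (!all(ok_h)) stop("invalid hemisphere values in region map", call. = FALSE)
  lateral <- map$hemisphere != "midline"
  ok_r <- map$region[lateral] %in% c("frontal", "central", "temporal", "occipital")
  if (!all(ok_r)) stop("lateral channels must have a valid region", call. = FALSE)
  if (any(!is.na(map$region[!lateral]))) {
    stop("midline channels must carry no region", call. = FALSE)
  }
  invisible(map)
}

#' Read / write a region map as TSV
#'
#' Tab-separated file with columns `channel`, `hemisphere`, `region`
#' (empty region for midline channels). Round-trips losslessly.
#'
#' @param map region map tibble (see [region_map()]).
#' @param path file path.
#' @return `read_region_map` returns the map tibble; `write_region_map`
#'   returns `path` invisibly.
#' @export
write_region_map <- function(map, path) {
  validate_region_map(map)
  out <- map
  out$region[is.na(out$region)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  df$region[df$region == ""] <- NA_character_
  map <- tibble::as_tibble(df)
  validate_region_map(map)
  map
}
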