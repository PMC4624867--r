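#' Per-subject network metrics table
#'
#' For each recording and band: band-wise PLI connectivity, the global
#' mean PLI, the weighted graph metrics C (mean clustering) and L
#' (characteristic path length), and optionally the 24 region-grouped
#' distance summaries as wide columns.
#'
#' @param recordings named list of [eeg_recording()] (names = subject ids).
#' @param bands character vector of shipped band names (or list of
#'   [band_definition()]).
#' @param map region map for the distance summaries; `NULL` derives one
#'   from the channel labels via [region_map()].
#' @param include_distance include the distance-summary columns?
#' @param matrix_sink optional function `(matrix, subject_id, band_name)`
#'   called with each connectivity matrix (used by [run_pipeline()] to
#'   write them out).
#' @return Tibble, one row per subject x band: `subject_id`, `band`,
#'   `global_mean_pli`, `C`, `L`, then one column per distance measure.
#' @export
subject_metrics <- function(recordings, bands = eeg_bands()$name,
                            map = NULL, include_distance = TRUE,
                            matrix_sink = NULL) {
  stopifnot(length(recordings) > 0, !is.null(names(recordings)))
  rows <- list()
  for (sid in names(recordings)) {
    rec <- recordings[[sid]]
    if (include_distance && is.null(map)) map <- region_map(rec$channel_labels)
    for (band in bands) {
      bd <- as_band(band)
      m <- connectivity_matrix(rec, bd)
      if (!is.null(matrix_sink)) matrix_sink(m, sid, bd$name)
      gm <- graph_metrics(unclass_matrix(m))
      row <- tibble::tibble(subject_id = sid, band = bd$name,
                            global_mean_pli = global_mean_pli(m),
                            C = gm$C, L = gm$L)
      if (include_distance) {
        ds <- distance_summary(m, map)
        ds <- ds[ds$measure != "global_mean", ]
        wide <- as.list(stats::setNames(ds$value, ds$measure))
        row <- cbind(row, tibble::as_tibble(wide))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

unclass_matrix <- function(m) {
  attr(m, "band") <- NULL
  class(m) <- "matrix"
  m <- unclass(m)
  m
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Exactly one input source must be given: a simulated cohort
#' (`simulation`), or recording files (`paths` + `format` + `manifest`).
#'
#' @param simulation a [cohort_spec()] (or a list accepted by
#'   [cohort_spec_from_list()]).
#' @param paths named character vector of recording files (names =
#'   subject ids).
#' @param format `"edf"` or `"delimited"` for file input.
#' @param fs_hz sampling rate for delimited input files.
#' @param manifest_path TSV manifest for file input (subject_id, group,
#'   score).
#' @param region_map_path optional region-map TSV; default derives the map
#'   from channel labels.
#' @param bands band names to analyze.
#' @param ref_labels,notch_hz,target_fs,segment_s,reject_threshold
#'   preprocessing toggles; `NULL` skips the corresponding step.
#' @param alpha,fdr statistics toggles (see [run_group_analysis()]).
#' @param out_dir output directory.
#' @param seed integer seed governing all randomness in the run.
#' @return A validated list with class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            format = c("delimited", "edf"), fs_hz = NULL,
                            manifest_path = NULL, region_map_path = NULL,
                            bands = eeg_bands()$name,
                            ref_labels = NULL, notch_hz = NULL,
                            target_fs = NULL, segment_s = NULL,
                            reject_threshold = NULL,
                            alpha = 0.05, fdr = FALSE,
                            out_dir = "plinet_out", seed = 1) {
  format <- match.arg(format)
  if (is.null(simulation) == is.null(paths)) {
    stop("exactly one input source required: `simulation` or `paths`",
         call. = FALSE)
  }
  if (!is.null(simulation) && !inherits(simulation, "cohort_spec")) {
    simulation <- cohort_spec_from_list(simulation)
  }
  if (!is.null(paths)) {
    if (is.null(names(paths)) || any(names(paths) == "")) {
      stop("`paths` must be named by subject id", call. = FALSE)
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (format == "delimited" && is.null(fs_hz)) {
      stop("`fs_hz` required for delimited input", call. = FALSE)
    }
    if (!is.null(manifest_path) && !file.exists(manifest_path)) {
      stop("manifest not found: ", manifest_path, call. = FALSE)
    }
  }
  if (!is.null(region_map_path) && !file.exists(region_map_path)) {
    stop("region map not found: ", region_map_path, call. = FALSE)
  }
  for (b in bands) as_band(b)   # validates names
  structure(
    list(simulation = simulation, paths = paths, format = format,
         fs_hz = fs_hz, manifest_path = manifest_path,
         region_map_path = region_map_path, bands = bands,
         ref_labels = ref_labels, notch_hz = notch_hz,
         target_fs = target_fs, segment_s = segment_s,
         reject_threshold = reject_threshold,
         alpha = alpha, fdr = fdr, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Rebuild simulation specs from plain lists
#'
#' Inverse of the YAML/JSON serialization of [coupling_spec()] /
#' [cohort_spec()]: reconstructs the spec objects from nested lists so a
#' configuration file can fully describe a simulated cohort.
#'
#' @param x nested list (e.g. from [yaml::read_yaml()]).
#' @return A [coupling_spec()] / [cohort_spec()].
#' @export
coupling_spec_from_list <- function(x) {
  edges <- x$edges
  if (!is.null(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e)
      data.frame(a = e$a, b = e$b, kappa = e$kappa, delta = e$delta)))
  }
  args <- x[setdiff(names(x), "edges")]
  do.call(coupling_spec, c(args, list(edges = edges)))
}

#' @rdname coupling_spec_from_list
#' @export
cohort_spec_from_list <- function(x) {
  base <- x$base_coupling
  if (!inherits(base, "coupling_spec")) base <- coupling_spec_from_list(base)
  args <- x[setdiff(names(x), "base_coupling")]
  do.call(cohort_spec, c(list(base_coupling = base), args))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; `.yaml`/`.yml` parsed with yaml, `.json` with
#'   jsonlite. The keys mirror the arguments of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$paths)) cfg$paths <- unlist(cfg$paths)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Simulate or load a cohort, apply the preprocessing chain
#' (re-reference, downsample, notch, artifact-aware segment extraction —
#' each step only if configured), compute the band-wise PLI connectivity
#' matrices, per-subject network metrics and the group/correlation
#' statistics, and write everything under `config$out_dir`:
#'
#' * `matrices/<subject>_<band>.tsv` — connectivity matrices
#' * `metrics.tsv` — per subject x band metrics table
#' * `manifest.tsv` — cohort manifest
#' * `global_pli_tests.tsv`, `distance_tests.tsv`, `graph_tests.tsv`,
#'   `correlations.tsv` — statistics reports
#' * `summary.json` — machine-readable statistics summary
#' * `run_manifest.json` — config echo, seed, package version and
#'   per-subject provenance, sufficient to reproduce the run
#'
#' Identical configurations (including seed) produce byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config.
#' @return Invisibly, a list with `metrics`, `stats`, `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    recordings <- cohort$recordings
    manifest <- cohort$manifest
  } else {
    recordings <- lapply(config$paths, read_recording,
                         format = config$format, fs_hz = config$fs_hz)
    names(recordings) <- names(config$paths)
    manifest <- if (!is.null(config$manifest_path)) {
      read_manifest(config$manifest_path)
    } else NULL
  }

  preprocess_one <- function(rec, sid) {
    step <- "preprocess"
    tryCatch({
      if (!is.null(config$ref_labels)) {
        step <- "rereference"; rec <- rereference(rec, config$ref_labels)
      }
      if (!is.null(config$target_fs)) {
        step <- "downsample"; rec <- downsample(rec, config$target_fs)
      }
      if (!is.null(config$notch_hz)) {
        step <- "notch"; rec <- notch(rec, config$notch_hz)
      }
      if (!is.null(config$segment_s)) {
        step <- "extract_segment"
        rec <- extract_segment(rec, config$segment_s,
                               config$reject_threshold)
      }
      rec
    }, error = function(e) {
      stop("stage '", step, "' failed for subject ", sid, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  recordings <- Map(preprocess_one, recordings, names(recordings))

  out_dir <- config$out_dir
  dir.create(file.path(out_dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  map <- if (!is.null(config$region_map_path)) {
    read_region_map(config$region_map_path)
  } else NULL

  sink <- function(m, sid, band) {
    write_pli_matrix_tsv(m, file.path(out_dir, "matrices",
                                      paste0(sid, "_", band, ".tsv")))
  }
  metrics <- tryCatch(
    subject_metrics(recordings, bands = config$bands, map = map,
                    matrix_sink = sink),
    error = function(e) stop("stage 'connectivity/graph' failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stats_out <- NULL
  if (!is.null(manifest)) {
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    stats_out <- run_group_analysis(metrics, manifest,
                                    alpha = config$alpha, fdr = config$fdr)
    for (fam in names(stats_out)) {
      if (is.null(stats_out[[fam]])) next
      utils::write.table(stats_out[[fam]],
                         file.path(out_dir, paste0(fam, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(stats_out, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  run_manifest <- list(
    package = "plinet",
    version = as.character(utils::packageVersion("plinet")),
    seed = config$seed,
    config = config_echo(config),
    provenance = lapply(recordings, `[[`, "provenance")
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, stats = stats_out,
                 manifest = manifest, out_dir = out_dir))
}

# serializable echo of a pipeline_config (specs flattened to plain lists)
config_echo <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) {
    sim <- unclass(cfg$simulation)
    base <- unclass(sim$base_coupling)
    base$edges <- lapply(seq_len(nrow(base$edges)), function(i)
      as.list(base$edges[i, ]))
    sim$base_coupling <- base
    cfg$simulation <- sim
  }
  cfg[!vapply(cfg, is.null, logical(1))]
}
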