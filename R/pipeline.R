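#' Default run configuration
#'
#' One configuration list governs a run; any subset may be overridden from a
#' YAML file ([read_config()]) or by argument. Parameter blocks mirror the
#' constructor arguments of [qc_params()], [deconv_params()],
#' [detection_params()] and [burst_definition()].
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    fs_hz = 10,
    output_dir = "calciburst-out",
    simulate = list(
      presets = c("TI-280", "TI-310"),
      n_roi = 20L,
      duration_s = 600,
      zg_area_um2 = 10000
    ),
    analyze = list(
      traces = NULL,                 # path(s) to long-format trace CSVs
      neuropil_coeff = 0.7,
      qc = list(), deconv = list(), detection = list(),
      burst = list(mode = "fixed", max_interval_s = 5.6, min_events = 3L),
      zg_area_um2 = 10000,
      window = list(start_s = 0, end_s = NULL, exclude = list())
    ),
    secretion = list(
      input = NULL,
      vehicle = "vehicle",
      per_animal = TRUE
    )
  )
}

#' Read a YAML run configuration
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "calci_io_error")
  }
  merge_cfg(default_config(), yaml::read_yaml(path))
}

merge_cfg <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_cfg(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

as_config <- function(config) {
  if (is.character(config)) return(read_config(config))
  merge_cfg(default_config(), config)
}

build_params <- function(block, constructor) {
  block <- block[intersect(names(block), names(formals(constructor)))]
  do.call(constructor, block)
}

write_manifest <- function(path, config, stage, files, counts) {
  manifest <- list(
    stage = stage,
    config_hash = rlang::hash(config),
    seed = config$seed,
    artifact_version = as.character(utils::packageVersion("calciburst")),
    files = files,
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Simulate datasets for every configured preset and write them to disk
#'
#' Writes, per preset, a long-format trace CSV (`roi_id`, `frame`, `F`,
#' `Fneu`) and a ground-truth JSON manifest, plus a run manifest carrying the
#' config hash, seed and per-preset counts. Deterministic under
#' `config$seed`.
#'
#' @param config A configuration list or YAML path (see [default_config()]).
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with the datasets and the manifest.
#' @export
run_simulate <- function(config = default_config(), output_dir = NULL) {
  config <- as_config(config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  presets <- config$simulate$presets
  if (length(presets) == 0) {
    abort("nothing to simulate: preset list is empty.",
          class = "calci_invalid_parameter")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  datasets <- list()
  files <- list()
  counts <- list()
  for (i in seq_along(presets)) {
    preset <- presets[[i]]
    message("simulate: preset ", preset)
    ds <- generate_dataset(
      preset, n_roi = config$simulate$n_roi,
      seed = config$seed + (i - 1L),
      duration_s = config$simulate$duration_s,
      fs_hz = config$fs_hz,
      zg_area_um2 = config$simulate$zg_area_um2
    )
    tr_path <- file.path(config$output_dir,
                         paste0("traces_", preset, ".csv"))
    gt_path <- file.path(config$output_dir,
                         paste0("ground_truth_", preset, ".json"))
    readr::write_csv(dplyr::select(ds$traces, -"time_s"), tr_path)
    jsonlite::write_json(
      list(condition = ds$condition, seed = ds$seed, fs_hz = ds$fs_hz,
           duration_s = ds$duration_s, zg_area_um2 = ds$zg_area_um2,
           roi = ds$ground_truth$roi, spikes = ds$ground_truth$spikes,
           bursts = ds$ground_truth$bursts),
      gt_path, auto_unbox = TRUE, digits = NA)
    datasets[[preset]] <- ds
    files[[preset]] <- list(traces = tr_path, ground_truth = gt_path)
    counts[[preset]] <- list(
      n_roi = nrow(ds$ground_truth$roi),
      n_active = sum(ds$ground_truth$roi$active),
      n_spikes = nrow(ds$ground_truth$spikes),
      n_bursts = nrow(ds$ground_truth$bursts)
    )
  }
  manifest <- write_manifest(
    file.path(config$output_dir, "simulate_manifest.json"),
    config, "simulate", files, counts)
  invisible(list(datasets = datasets, manifest = manifest))
}

# Restrict events to the analysis window; returns the filtered events and the
# total included duration used for time-normalized metrics.
apply_window <- function(events, window, duration_s) {
  start_s <- window$start_s %||% 0
  end_s <- window$end_s %||% duration_s
  keep <- events$peak_time_s >= start_s & events$peak_time_s <= end_s
  included <- end_s - start_s
  for (span in window$exclude %||% list()) {
    lo <- span[[1]]; hi <- span[[2]]
    keep <- keep & !(events$peak_time_s >= lo & events$peak_time_s <= hi)
    included <- included - max(0, min(hi, end_s) - max(lo, start_s))
  }
  list(events = events[keep, ], duration_s = included)
}

#' Run the full trace-analysis pipeline
#'
#' Reads long-format trace CSVs, then runs the fixed stage order per ROI:
#' neuropil subtraction, rolling-baseline detrending, SD-ratio QC, sparse
#' nonnegative deconvolution, dual-threshold transient detection, template
#' validation, analysis-window filtering, burst segmentation (with a fixed
#' threshold or one fitted from the pooled interpeak intervals), and
#' activity metrics. Writes events, bursts, QC report, per-ROI and per-slice
#' metrics, binned frequencies, a mixture report and a run manifest.
#'
#' @param config A configuration list or YAML path; `config$analyze$traces`
#'   must name at least one existing CSV.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a named list (one entry per input file) of lists with
#'   `processed`, `events`, `bursts`, `metrics`, `threshold_s`, `mixture`.
#' @export
run_analyze <- function(config, output_dir = NULL) {
  config <- as_config(config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  paths <- config$analyze$traces
  if (is.null(paths) || length(paths) == 0) {
    abort("no input traces configured.", class = "calci_io_error")
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("input trace file(s) not found: ",
                 paste(missing, collapse = ", ")), class = "calci_io_error")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- build_params(config$analyze$qc, qc_params)
  dcp <- build_params(config$analyze$deconv, deconv_params)
  det <- build_params(config$analyze$detection, detection_params)
  fs <- config$fs_hz

  results <- list()
  files <- list()
  counts <- list()
  for (path in paths) {
    label <- sub("\\.csv$", "", basename(path))
    message("analyze: ", label)
    traces <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("roi_id", "frame", "F") %in% names(traces))) {
      abort(paste0("malformed trace CSV (need roi_id, frame, F): ", path),
            class = "calci_io_error")
    }
    n_roi_in <- dplyr::n_distinct(traces$roi_id)
    duration_s <- max(traces$frame) / fs

    processed <- preprocess_traces(traces, fs_hz = fs,
                                   neuropil_coeff = config$analyze$neuropil_coeff,
                                   qc = qc, deconv = dcp)
    n_roi_qc <- dplyr::n_distinct(processed$traces$roi_id)
    if (n_roi_qc < n_roi_in) {
      warn(paste0(label, ": ", n_roi_in - n_roi_qc, " ROI(s) excluded by QC."))
    }
    if (n_roi_qc == 0) {
      warn(paste0(label, ": all ROIs failed QC; emitting empty metrics."))
    }
    events <- detect_transients(processed, det)
    events <- validate_transients(events, processed, params = det)
    if (nrow(events) > 0 && mean(events$validated) < 0.5) {
      warn(paste0(label, ": more than 50% of events failed validation."))
    }
    win <- apply_window(events, config$analyze$window, duration_s)
    ev_use <- dplyr::filter(win$events, .data$validated)

    bcfg <- config$analyze$burst
    mixture <- NULL
    if (identical(bcfg$mode, "fit")) {
      ints <- ev_use |>
        dplyr::group_by(.data$roi_id) |>
        dplyr::reframe(interval_s = diff(.data$peak_time_s))
      mixture <- fit_interval_mixture(ints$interval_s)
      threshold_s <- mixture_intersection(mixture)
    } else {
      threshold_s <- bcfg$max_interval_s %||% 5.6
    }
    defn <- burst_definition(threshold_s, bcfg$min_events %||% 3L)
    bursts <- segment_bursts(ev_use, defn)
    metrics <- compute_metrics(ev_use, bursts, win$duration_s,
                               zg_area_um2 = config$analyze$zg_area_um2 %||%
                                 NA_real_,
                               roi_ids = unique(processed$traces$roi_id))

    out <- function(nm) file.path(config$output_dir,
                                  paste0(label, "_", nm))
    readr::write_csv(win$events, out("events.csv"))
    readr::write_csv(dplyr::select(bursts, -"event_times_s"),
                     out("bursts.csv"))
    readr::write_csv(processed$qc, out("qc.csv"))
    readr::write_csv(metrics$per_roi, out("metrics_roi.csv"))
    readr::write_csv(metrics$slice, out("metrics_slice.csv"))
    readr::write_csv(metrics$binned, out("binned_frequency.csv"))
    jsonlite::write_json(
      list(threshold_s = threshold_s,
           mode = bcfg$mode %||% "fixed",
           mixture = if (!is.null(mixture)) unclass(mixture)),
      out("mixture.json"), auto_unbox = TRUE, digits = NA)

    results[[label]] <- list(processed = processed, events = win$events,
                             bursts = bursts, metrics = metrics,
                             threshold_s = threshold_s, mixture = mixture)
    files[[label]] <- list(input = path, events = out("events.csv"),
                           bursts = out("bursts.csv"), qc = out("qc.csv"))
    counts[[label]] <- list(
      n_roi_in = n_roi_in, n_roi_qc = n_roi_qc,
      n_events = nrow(win$events),
      n_validated = sum(win$events$validated),
      n_bursts = nrow(bursts)
    )
  }
  write_manifest(file.path(config$output_dir, "analyze_manifest.json"),
                 config, "analyze", files, counts)
  invisible(results)
}

#' Run the secretion normalization and dose-response fit
#'
#' Reads a per-slice secretion CSV (columns as in [normalize_secretion()]
#' plus `osmolarity_mOsm`), normalizes fold changes, averages replicate
#' slices per animal and condition, and fits the sigmoidal
#' osmolarity-response curve to the normalized folds.
#'
#' @param config A configuration list or YAML path;
#'   `config$secretion$input` must name an existing CSV.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with `normalized`, `per_animal`, `fit`.
#' @export
run_secretion <- function(config, output_dir = NULL) {
  config <- as_config(config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  path <- config$secretion$input
  if (is.null(path) || !file.exists(path)) {
    abort(paste0("secretion input not found: ", path %||% "<unset>"),
          class = "calci_io_error")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  records <- readr::read_csv(path, show_col_types = FALSE)
  normalized <- normalize_secretion(records,
                                    vehicle = config$secretion$vehicle)
  per_animal <- summarize_secretion(normalized, .data$osmolarity_mOsm)
  treated <- dplyr::filter(per_animal,
                           .data$treatment != config$secretion$vehicle)
  fit_data <- if (isTRUE(config$secretion$per_animal)) treated else
    dplyr::filter(normalized, .data$treatment != config$secretion$vehicle)
  fit <- if (nrow(fit_data) >= 5 &&
             dplyr::n_distinct(fit_data$osmolarity_mOsm) >= 3) {
    fit_sigmoid(fit_data, osmolarity_mOsm, fold_norm)
  } else NULL
  readr::write_csv(normalized,
                   file.path(config$output_dir, "secretion_normalized.csv"))
  readr::write_csv(per_animal,
                   file.path(config$output_dir, "secretion_per_animal.csv"))
  if (!is.null(fit)) {
    jsonlite::write_json(
      list(coef = as.list(fit$coef), r_squared = fit$r_squared,
           converged = fit$converged, form = fit$form),
      file.path(config$output_dir, "secretion_fit.json"),
      auto_unbox = TRUE, digits = NA)
  }
  write_manifest(file.path(config$output_dir, "secretion_manifest.json"),
                 config, "secretion",
                 list(input = path),
                 list(n_slices = nrow(records),
                      n_normalized = nrow(normalized)))
  invisible(list(normalized = normalized, per_animal = per_animal, fit = fit))
}
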