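#' Default analysis parameters
#'
#' Single source of truth for every tunable analysis parameter. Values not
#' overridden in a run configuration are taken from here, and the full
#' realized set is echoed into the provenance record of every pipeline run.
#'
#' @return named list of defaults, grouped by stage.
#' @export
optopace_defaults <- function() {
  list(
    ecg = list(
      passband_hz = 100,          # lowpass passband edge
      invert = FALSE,
      min_height = 0.4,           # R-peak threshold, normalized units
      min_separation_ms = 50,     # R-peak spacing
      p_search_window_ms = 100,   # P-wave search before the R peak
      p_guard_ms = 10,            # blanking just before the R peak
      p_min_prominence = 0.1,
      zero_cross_span_ms = 60,    # crossing search span around the R peak
      ttl_threshold = 0.5,
      window_ventricular_ms = c(10, 38),
      window_nodal_ms = c(38, 52)
    ),
    vessel = list(
      band_width_um = 28.05,      # profile averaging band
      search_radius_px = 20,      # stabilization shift search
      fit_window = 3,             # quadratic peak refinement samples
      smooth_window_frames = 5,   # running average
      min_search_s = 10,          # reference extremum window after onset
      direction = "dilation"
    ),
    gate = list(
      n_bins = 10,
      exclusion_fraction = 0.3,   # respiratory rejection window
      min_resp_period_s = 0.25
    ),
    fluor = list(
      detect_threshold = 0.2,
      match_window_ms = 200,
      detrend_window_s = 1,
      min_sustain_ms = 20
    )
  )
}

#' Build and validate a run configuration
#'
#' Merges user settings over [optopace_defaults()], rejecting any key that
#' is not a known parameter so that typos fail loudly instead of silently
#' using a default.
#'
#' @param config named list of overrides, or a path to a YAML/JSON file
#'   containing one. Top level may contain the stage groups of
#'   [optopace_defaults()] plus `stage`, `seed`, `inputs`, `out_dir`.
#' @return list of class `run_config` with all defaults realized.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- optopace_defaults()
  known_top <- c(names(defaults), "stage", "seed", "inputs", "out_dir")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  merged <- defaults
  for (grp in names(defaults)) {
    if (is.null(config[[grp]])) next
    bad <- setdiff(names(config[[grp]]), names(defaults[[grp]]))
    if (length(bad))
      stop(sprintf("unknown configuration key(s) in `%s`: %s", grp,
                   paste(bad, collapse = ", ")), call. = FALSE)
    merged[[grp]][names(config[[grp]])] <- config[[grp]]
  }
  merged$stage <- config$stage
  merged$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  merged$inputs <- config$inputs
  merged$out_dir <- config$out_dir
  class(merged) <- "run_config"
  merged
}

#' Full ECG pacing analysis
#'
#' Runs the complete beat pipeline on a raw ECG and laser TTL recording:
#' preprocessing ([preprocess_ecg()]), pulse binarization
#' ([binarize_pulses()]), R- and P-peak detection, latency-window beat
#' classification ([classify_beats()]), and zero-crossing interval
#' measurement ([measure_intervals()]).
#'
#' @param ecg_raw raw ECG [time_trace()].
#' @param ttl_raw raw laser TTL [time_trace()].
#' @param mode `"ventricular"` or `"nodal"`.
#' @param params `ecg` parameter group (see [optopace_defaults()]); partial
#'   overrides allowed.
#' @param r_peaks optional manually curated R-peak times (s); skips
#'   automatic detection when supplied.
#' @return list with `beats` (measured, classified [beat_table()]),
#'   `pulses` ([pulse_train()]), `ecg` (preprocessed trace), `r_peaks`.
#' @export
analyze_ecg <- function(ecg_raw, ttl_raw, mode = c("ventricular", "nodal"),
                        params = list(), r_peaks = NULL) {
  mode <- match.arg(mode)
  p <- optopace_defaults()$ecg
  bad <- setdiff(names(params), names(p))
  if (length(bad))
    stop("unknown ECG parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p[names(params)] <- params

  ecg <- preprocess_ecg(ecg_raw, passband = p$passband_hz,
                        invert = isTRUE(p$invert))
  pulses <- binarize_pulses(ttl_raw, threshold_fraction = p$ttl_threshold)
  if (is.null(r_peaks))
    r_peaks <- detect_r_peaks(ecg, min_height = p$min_height,
                              min_separation = p$min_separation_ms)
  p_times <- detect_p_waves(ecg, r_peaks,
                            search_window = p$p_search_window_ms,
                            guard = p$p_guard_ms,
                            min_prominence = p$p_min_prominence)
  beats <- beat_table(r_peaks, p_times)
  win <- if (mode == "ventricular") p$window_ventricular_ms
         else p$window_nodal_ms
  beats <- classify_beats(beats, pulses, mode, window = win)
  beats <- measure_intervals(ecg, beats, search_span = p$zero_cross_span_ms)
  list(beats = beats, pulses = pulses, ecg = ecg, r_peaks = r_peaks)
}

#' Compare an interval between stimulated and unstimulated beats
#'
#' Two-sided Mann-Whitney comparison of a measured interval between the
#' stimulated and unstimulated beat classes of a classified, measured
#' beat table.
#'
#' @param beats a [beat_table()] after [classify_beats()] and
#'   [measure_intervals()].
#' @param measure `"r_duration_ms"` or `"pr_interval_ms"`.
#' @return list: `u`, `p_value`, `exact`, `n_stimulated`, `n_unstimulated`,
#'   `median_stimulated`, `median_unstimulated`.
#' @export
compare_beat_classes <- function(beats,
                                 measure = c("r_duration_ms",
                                             "pr_interval_ms")) {
  measure <- match.arg(measure)
  stopifnot(inherits(beats, "beat_table"))
  s <- beats[[measure]][beats$label == "stimulated"]
  u <- beats[[measure]][beats$label == "unstimulated"]
  s <- s[!is.na(s)]; u <- u[!is.na(u)]
  if (!length(s) || !length(u))
    stop("need measured beats in both classes", call. = FALSE)
  mw <- mann_whitney_u(s, u)
  c(mw, list(n_stimulated = length(s), n_unstimulated = length(u),
             median_stimulated = stats::median(s),
             median_unstimulated = stats::median(u)))
}

#' Run a configured pipeline stage and write outputs with provenance
#'
#' Executes the stage named in the configuration (`"ecg"` or `"vessel"`)
#' on the configured input files, writes the stage outputs into `out_dir`,
#' and drops a JSON provenance record (`provenance.json`) carrying the
#' realized configuration, its hash, the seed, and the package version.
#'
#' @param config a [run_config()], a list of overrides, or a YAML/JSON
#'   path.
#' @return list of output file paths plus the in-memory results, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(cfg$stage) || !cfg$stage %in% c("ecg", "vessel"))
    stop("config must name a stage: \"ecg\" or \"vessel\"", call. = FALSE)
  if (is.null(cfg$out_dir)) stop("config must set `out_dir`", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  outputs <- list()
  if (cfg$stage == "ecg") {
    ins <- cfg$inputs
    for (f in c("ecg_csv", "ttl_csv", "mode"))
      if (is.null(ins[[f]]))
        stop("ecg stage: missing input `", f, "`", call. = FALSE)
    res <- analyze_ecg(read_time_trace(ins$ecg_csv),
                       read_time_trace(ins$ttl_csv),
                       mode = ins$mode, params = cfg$ecg)
    beats_path <- file.path(cfg$out_dir, "beats.csv")
    write_beat_table(res$beats, beats_path)
    outputs <- list(beats_csv = beats_path, result = res)
  } else {
    ins <- cfg$inputs
    for (f in c("stack_tiff", "line"))
      if (is.null(ins[[f]]))
        stop("vessel stage: missing input `", f, "`", call. = FALSE)
    stack <- tryCatch(read_stack(ins$stack_tiff), error = function(e)
      stop("vessel stage expects a multi-page TIFF stack with JSON ",
           "sidecar; could not read `", ins$stack_tiff, "`: ",
           conditionMessage(e), call. = FALSE))
    stab <- stabilize_stack(stack,
                            search_radius = cfg$vessel$search_radius_px)
    line <- matrix(unlist(ins$line), 2, 2, byrow = TRUE)
    trace <- diameter_series(stab$stack, line,
                             band_width = cfg$vessel$band_width_um,
                             fit_window = cfg$vessel$fit_window)
    sm <- smooth_running_average(trace, cfg$vessel$smooth_window_frames)
    trace_path <- file.path(cfg$out_dir, "diameter.csv")
    utils::write.csv(as.data.frame(sm), trace_path, row.names = FALSE)
    outputs <- list(diameter_csv = trace_path, trace = sm,
                    shifts = stab$shifts)
    if (!is.null(ins$laser_on) && !is.null(ins$laser_off)) {
      rm_ <- response_metrics(sm, ins$laser_on, ins$laser_off,
                              min_search = cfg$vessel$min_search_s,
                              direction = cfg$vessel$direction)
      metrics_path <- file.path(cfg$out_dir, "response_metrics.json")
      jsonlite::write_json(
        rm_[c("min_width_um", "max_width_um", "pct_change", "direction")],
        metrics_path, auto_unbox = TRUE, digits = NA)
      outputs$metrics_json <- metrics_path
      outputs$metrics <- rm_
    }
  }
  prov <- list(
    stage = cfg$stage,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("optopace")),
    config = unclass(cfg)[setdiff(names(cfg), "inputs")],
    inputs = cfg$inputs,
    config_hash = config_hash(cfg)
  )
  prov_path <- file.path(cfg$out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  outputs$provenance_json <- prov_path
  invisible(outputs)
}

## md5 of the canonical JSON serialization of the realized configuration
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}
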