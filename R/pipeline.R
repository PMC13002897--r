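#' Run configuration for the end-to-end pipeline
#'
#' A plain named list validated by [run_pipeline()]; [read_run_config()]
#' loads one from YAML. Core fields:
#'
#' * `seed`: integer; every source of randomness flows from it.
#' * `out_dir`: output directory.
#' * `analysis`: `"seizure"` (LFP band, SR/FPSR/stats) or `"spikes"`
#'   (spike band, detection/quality/rates).
#' * `simulate`: list of [sim_config()] overrides (generates the input), or
#'   `recording`: path base of an existing recording (with `schedule` and
#'   optionally `layout` paths).
#' * `schedule`: when simulating, a list
#'   `list(type = "cw"|"pulse_train", ...args)` forwarded to
#'   [make_cw_schedule()] / [make_pulse_train_schedule()].
#' * `bad_channels`, `blank_ms`, `pre_s`, `post_s`, `baseline_s`,
#'   `window_ms`, `pulse_offset_ms`: analysis parameters.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "probeseize_missing_file")
  }
  yaml::read_yaml(path)
}

config_hash <- function(config) {
  # hash of the analysis configuration; the output location is not part of it
  config <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "probeseize_stage_error", parent = e)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or reading from disk),
#' preprocessing (common average referencing, bandpass, artifact blanking),
#' and either the seizure analysis (per-pattern SR matrices, FPSR,
#' pre/during/post Mann-Whitney tests) or the spiking analysis (threshold
#' detection, quality gating, firing rates, in-pulse fractions). Results are
#' written under `out_dir` and summarized in a report; given the same config
#' and seed the written outputs are byte-identical across runs.
#'
#' @param config a named list (see [read_run_config()]).
#' @return list of class `probeseize_report`: `provenance` (config hash,
#'   package version, seed), `stages` (per-stage summaries), `results`
#'   (in-memory analysis tables), `manifest` (paths written).
#' @export
run_pipeline <- function(config) {
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("probeseize_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analysis <- match.arg(config$analysis %||% "seizure", c("seizure", "spikes"))
  manifest <- character()
  stages <- list()

  layout <- pipeline_stage("layout", {
    if (!is.null(config$layout)) read_layout(config$layout) else default_layout()
  })

  acq <- pipeline_stage("acquire", {
    if (!is.null(config$simulate)) {
      sched_cfg <- config$schedule %||% list(type = "cw")
      type <- sched_cfg$type %||% "cw"
      sched_args <- sched_cfg[setdiff(names(sched_cfg), "type")]
      sched_args$seed <- sched_args$seed %||% seed
      if (is.null(sched_args$emitters)) {
        sched_args$emitters <- layout$emitters$emitter_id
      }
      schedule <- do.call(
        if (type == "cw") make_cw_schedule else make_pulse_train_schedule,
        sched_args
      )
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      if (is.null(sim_args$duration_s)) {
        sim_args$duration_s <- schedule_end(schedule) + 10
      }
      if (!is.null(sim_args$units) && !inherits(sim_args$units, "tbl_df")) {
        sim_args$units <- do.call(unit_table, sim_args$units)
      }
      if (!is.null(sim_args$seizure) && is.list(sim_args$seizure)) {
        sim_args$seizure <- do.call(seizure_config, sim_args$seizure)
      }
      sim <- simulate_recording(do.call(sim_config, sim_args), schedule, layout)
      write_schedule(schedule, file.path(out_dir, "schedule.csv"))
      manifest <- c(manifest, file.path(out_dir, "schedule.csv"))
      list(recording = sim$recording, schedule = schedule,
           ground_truth = sim$ground_truth)
    } else if (!is.null(config$recording)) {
      list(recording = read_recording(config$recording, layout = layout),
           schedule = read_schedule(config$schedule),
           ground_truth = NULL)
    } else {
      abort("config needs either `simulate` or `recording`",
            class = "probeseize_invalid_config")
    }
  })
  stages$acquire <- list(
    n_channels = n_channels(acq$recording),
    n_samples = n_samples(acq$recording),
    rate_hz = acq$recording$rate_hz,
    n_pulses = nrow(acq$schedule$pulses)
  )

  band <- if (analysis == "seizure") "lfp" else "spike"
  rec <- pipeline_stage("preprocess", {
    preprocess(acq$recording, acq$schedule, band = band,
               bad_channels = as.integer(config$bad_channels %||% integer()),
               blank_ms = config$blank_ms %||% 5)
  })
  stages$preprocess <- list(band = band, steps = rec$steps,
                            bad_channels = rec$bad_channels)

  results <- list()
  if (analysis == "seizure") {
    results <- pipeline_stage("seizure_analysis", {
      srs <- sr_matrices(rec, acq$schedule, pre_s = config$pre_s)
      fps <- dplyr::bind_rows(lapply(srs, fpsr))
      powers <- pre_dur_post_powers(rec, acq$schedule, pre_s = config$pre_s,
                                    post_s = config$post_s)
      test <- pre_dur_post_test(
        powers$p_uv2[powers$phase == "pre"],
        powers$p_uv2[powers$phase == "during"],
        powers$p_uv2[powers$phase == "post"]
      )
      for (nm in names(srs)) {
        f <- file.path(out_dir, paste0("sr_matrix_", nm, ".csv"))
        write_sr_matrix(srs[[nm]], f)
        manifest <- c(manifest, f)
      }
      f <- file.path(out_dir, "fpsr.json")
      jsonlite::write_json(fps, f, auto_unbox = TRUE, digits = NA)
      manifest <- c(manifest, f)
      f <- file.path(out_dir, "power_tests.csv")
      readr::write_csv(test, f)
      manifest <- c(manifest, f)
      list(sr_matrices = srs, fpsr = fps, powers = powers, tests = test)
    })
    stages$analysis <- list(kind = "seizure", n_patterns = length(results$sr_matrices),
                            spike_analysis = "skipped (lfp band)")
  } else {
    results <- pipeline_stage("spike_analysis", {
      trains <- detect_spikes(rec,
                              threshold_mads = config$threshold_mads %||% 5)
      quality <- unit_quality(trains)
      rates <- firing_rates(trains, acq$schedule,
                            baseline_s = config$baseline_s %||% 10)
      fip <- fraction_in_pulse(trains, acq$schedule,
                               window_s = (config$window_ms %||% 230) / 1000,
                               pulse_offset_s = (config$pulse_offset_ms %||% 100) / 1000)
      for (nm in c("quality", "rates", "fip")) {
        f <- file.path(out_dir, paste0(nm, ".csv"))
        readr::write_csv(get(nm), f)
        manifest <- c(manifest, f)
      }
      list(spike_trains = trains, quality = quality, rates = rates,
           fraction_in_pulse = fip)
    })
    stages$analysis <- list(kind = "spikes",
                            n_units_pass = sum(results$quality$passes))
  }

  report <- structure(
    list(
      provenance = list(config_hash = config_hash(config),
                        package_version = as.character(utils::packageVersion("probeseize")),
                        seed = seed),
      stages = stages,
      results = results,
      manifest = manifest
    ),
    class = "probeseize_report"
  )
  report_file <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(provenance = report$provenance, stages = stages,
         manifest = basename(manifest)),
    report_file, auto_unbox = TRUE, digits = NA, force = TRUE
  )
  report$manifest <- c(report$manifest, report_file)
  missing <- report$manifest[!file.exists(report$manifest)]
  if (length(missing)) {
    abort(paste0("pipeline finished but outputs are missing: ",
                 paste(missing, collapse = ", ")),
          class = "probeseize_stage_error")
  }
  report
}

#' @export
print.probeseize_report <- function(x, ...) {
  cat(sprintf("<probeseize_report> seed %d, %d output files\n",
              x$provenance$seed, length(x$manifest)))
  invisible(x)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report (or its written JSON) for the required fields and types
#' declared in `inst/schema/report-schema.json`.
#'
#' @param report a `probeseize_report` or path to a `report.json`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_report <- function(report) {
  obj <- if (is.character(report)) jsonlite::read_json(report, simplifyVector = TRUE) else report
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "probeseize"),
    simplifyVector = TRUE
  )
  req <- schema$required
  missing <- setdiff(req, names(obj))
  if (length(missing)) {
    abort(paste0("report is missing fields: ", paste(missing, collapse = ", ")),
          class = "probeseize_invalid_report")
  }
  prov_req <- schema$properties$provenance$required
  missing_p <- setdiff(prov_req, names(obj$provenance))
  if (length(missing_p)) {
    abort(paste0("report provenance is missing: ", paste(missing_p, collapse = ", ")),
          class = "probeseize_invalid_report")
  }
  invisible(TRUE)
}
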