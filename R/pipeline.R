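# Pipeline orchestration: power-line cancellation -> SMP regression ->
# EMG spike reduction -> time-frequency analysis -> epoch rejection ->
# ERS statistics, with every stage's output written to new files (inputs
# are never mutated) and a machine-readable run log.

#' Pipeline configuration
#'
#' Stage order is fixed to powerline, smp, emg, tfr, reject, ers unless a
#' subset is requested; defaults equal the standard analysis parameters
#' (7 muV change threshold, correlation gate by sampling rate, a = 1.5,
#' b = 0.06, cap 0.4 muV/Hz, 65-85 and 60-130 Hz bands).
#'
#' @param input path to a recording (`.edf` or delimited `.txt`), or an
#'   [recording()] object.
#' @param events path to an events CSV, or an [event_series()].
#' @param out_dir output directory (created if missing).
#' @param stages character subset of
#'   `c("powerline","smp","emg","tfr","reject","ers")`, kept in canonical
#'   order.
#' @param powerline,smp,emg,reject,ers per-stage parameter lists (see
#'   [cancel_powerline()], [fit_smp()], [detection_config()],
#'   [rejection_config()], [trial_band_amplitudes()]).
#' @param derivation `c(anode, cathode)` for the analysis derivation.
#' @param write_edf_outputs write corrected recordings as EDF instead of
#'   text.
#' @param seed RNG seed recorded in the run log.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, events, out_dir,
                            stages = c("powerline", "smp", "emg", "tfr",
                                       "reject", "ers"),
                            powerline = list(noise_ref = "MAINS", f0 = 50),
                            smp = list(ref_labels = c("SMPL", "SMPR")),
                            emg = list(),
                            reject = list(),
                            ers = list(band = c(65, 85), peak_window = c(0, 0.25)),
                            derivation = c("C3", "CZ"),
                            write_edf_outputs = FALSE,
                            seed = 1L) {
  order_ <- c("powerline", "smp", "emg", "tfr", "reject", "ers")
  stages <- order_[order_ %in% stages]
  if (!length(stages)) stop("no valid stages requested")
  structure(list(input = input, events = events, out_dir = out_dir,
                 stages = stages, powerline = powerline, smp = smp,
                 emg = emg, reject = reject, ers = ers,
                 derivation = derivation,
                 write_edf_outputs = write_edf_outputs, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

load_input_recording <- function(input) {
  if (inherits(input, "eeg_recording")) return(input)
  if (grepl("\\.edf$", input, ignore.case = TRUE)) read_edf(input) else
    read_recording_txt(input)
}

#' Run the artifact-reduction pipeline
#'
#' Executes the configured stages in order and writes, per stage, a
#' suffixally named corrected recording, plus the spike inventory CSV, the
#' epoch mask CSV, the ERS results CSV and a JSON run log with parameters,
#' seed and per-stage summary statistics.  Any stage failure aborts with
#' the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list of result objects and output paths, invisibly; the run log
#'   is also returned under `$log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- load_input_recording(config$input)
  events <- if (inherits(config$events, "event_series")) config$events else
    read_events_csv(config$events)
  set.seed(config$seed)
  log <- list(seed = config$seed, stages = config$stages,
              fs = rec$fs, n_channels = length(rec$channel_labels),
              n_samples = ncol(rec$samples), stage_summaries = list())
  out <- list()
  artifacts <- character()
  write_rec <- function(r, name) {
    p <- file.path(config$out_dir,
                   paste0(name, if (config$write_edf_outputs) ".edf" else ".txt"))
    if (config$write_edf_outputs) write_edf(r, p) else write_recording_txt(r, p)
    artifacts <<- c(artifacts, p)
    p
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  aux <- setdiff(rec$channel_labels,
                 union(config$smp$ref_labels %||% character(), "MAINS"))

  if ("powerline" %in% config$stages) run_stage("powerline", function() {
    args <- c(list(rec = rec), config$powerline)
    if (!is.null(args$noise_ref) && !args$noise_ref %in% rec$channel_labels)
      args$noise_ref <- NULL
    pl <- do.call(cancel_powerline, args)
    rec <<- pl$recording
    out$powerline <<- pl
    log$stage_summaries$powerline <<- list(K = pl$K, f0 = pl$f0)
    write_rec(rec, "01_powerline")
  })

  if ("smp" %in% config$stages &&
      all((config$smp$ref_labels %||% c("SMPL", "SMPR")) %in% rec$channel_labels))
    run_stage("smp", function() {
      model <- do.call(fit_smp, c(list(rec = rec), config$smp))
      rec <<- apply_smp(rec, model)
      out$smp <<- model
      log$stage_summaries$smp <<- list(mean_abs_weight = mean(abs(model$weights)))
      write_rec(rec, "02_smp")
    })
  rec_pre_emg <- rec

  if ("emg" %in% config$stages) run_stage("emg", function() {
    cfg <- do.call(detection_config, c(list(fs = rec$fs), config$emg))
    res <- reduce_emg(rec, cfg, channels = aux)
    rec <<- res$recording
    out$emg <<- res
    p <- file.path(config$out_dir, "spike_inventory.csv")
    utils::write.csv(res$spikes, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    log$stage_summaries$emg <<- list(n_spikes = nrow(res$spikes))
    write_rec(rec, "03_emg")
  })

  if ("tfr" %in% config$stages) run_stage("tfr", function() {
    x <- derive_bipolar(rec, config$derivation[1L], config$derivation[2L])
    map <- sliding_fft_amplitude(x, rec$fs, fmax = 140,
                                 derivation = paste(config$derivation, collapse = "-"))
    out$tfr <<- map
    p <- file.path(config$out_dir, "tfmap")
    write_tf_map(map, p)
    artifacts <<- c(artifacts, paste0(p, c(".txt", ".json")))
    log$stage_summaries$tfr <<- list(n_windows = nrow(map$amplitudes),
                                     window_samples = map$window_samples)
  })

  trials_pre <- trials_post <- NULL
  mask <- NULL
  if ("reject" %in% config$stages) run_stage("reject", function() {
    # mask decided on the post-SMP / pre-EMG condition
    cfg <- do.call(rejection_config, config$reject)
    wide <- do.call(trial_band_amplitudes,
                    list(rec_pre_emg, events, config$derivation[1L],
                         config$derivation[2L], band = c(60, 130)))
    gam <- do.call(trial_band_amplitudes,
                   list(rec_pre_emg, events, config$derivation[1L],
                        config$derivation[2L], band = c(65, 85)))
    m <- build_mask(rowMeans(cbind(wide$peak, wide$baseline), na.rm = TRUE), cfg)
    m <- anomaly_reject(gam$max_band, m, cfg)
    mask <<- m
    p <- file.path(config$out_dir, "epoch_mask.csv")
    write_mask_csv(m, p)
    artifacts <<- c(artifacts, p)
    log$stage_summaries$reject <<- list(threshold = m$threshold_used,
                                        n_rejected = sum(!m$keep))
  })

  if ("ers" %in% config$stages) run_stage("ers", function() {
    band <- config$ers$band %||% c(65, 85)
    pw <- config$ers$peak_window %||% c(0, 0.25)
    trials_post <<- trial_band_amplitudes(rec, events, config$derivation[1L],
                                          config$derivation[2L],
                                          band = band, peak_window = pw)
    res <- ers_test(trials_post$peak, trials_post$baseline, mask)
    out$ers <<- res
    p <- file.path(config$out_dir, "ers_results.csv")
    utils::write.csv(data.frame(derivation = paste(config$derivation, collapse = "-"),
                                n = res$n, mean_baseline_uv_hz = res$mean_baseline,
                                mean_peak_uv_hz = res$mean_peak,
                                mean_ers_uv_hz = res$mean_ers,
                                t = res$t, p = res$p, tail = res$tail),
                     p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    log$stage_summaries$ers <<- list(t = res$t, p = res$p, n = res$n)
  })

  log$artifacts <- artifacts
  logp <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, logp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$log <- log
  out$mask <- mask
  out$recording <- rec
  invisible(out)
}
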