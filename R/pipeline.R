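#' Persist / restore a trained classifier
#'
#' The model is written as a binary RDS with a JSON metadata sidecar
#' (`<path>.json`) recording the bin count, training-set size, seed and
#' training accuracy, so a stored model's STFT geometry can be checked
#' without loading it.
#'
#' @param model a `click_classifier`.
#' @param path output path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "click_classifier"))
  saveRDS(model, path)
  jsonlite::write_json(
    c(list(format_version = 1L, n_bins = model$n_bins), model$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "click_classifier")) stop("not a click_classifier: ", path)
  model
}

write_manifest <- function(out_dir, stage, row_counts, config = NULL,
                           inputs = character(0)) {
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  manifest <- list(
    tool = paste0("finclick ", as.character(utils::packageVersion("finclick"))),
    stage = stage, timestamp = format(Sys.time(), tz = "UTC"),
    config_md5 = cfg_hash,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    row_counts = row_counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate stage: write a ground-truthed recording and count tables
#'
#' Renders a synthetic WAV with known click times, writes the ground-truth
#' click list, and simulates the minute-level count and annotation tables
#' of the scenario. All outputs are deterministic in the scenario seed.
#'
#' @param out_dir output directory (created if needed).
#' @param scenario a [scenario_config()].
#' @param audio list of render settings: `duration` (s), `sample_rate`,
#'   `train_rate_per_min`, `snr_db`, `noise_level_db`, `echo_model`.
#' @return invisibly, the list of written file paths.
#' @export
run_simulate <- function(out_dir, scenario = scenario_config(),
                         audio = list(duration = 10, sample_rate = 576000,
                                      train_rate_per_min = 20,
                                      snr_db = c(12, 25),
                                      noise_level_db = -40,
                                      echo_model = FALSE)) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir)
  }
  clicks <- generate_click_times(
    clip_duration = audio$duration,
    train_rate_per_min = audio$train_rate_per_min,
    snr_db = audio$snr_db, seed = scenario$seed)
  rec <- render_recording(clicks, audio$duration, audio$sample_rate,
                          noise_level_db = audio$noise_level_db,
                          echo_model = isTRUE(audio$echo_model),
                          seed = scenario$seed + 1L)
  sim <- generate_minute_counts(scenario)

  paths <- list(
    wav = file.path(out_dir, "recording.wav"),
    truth = file.path(out_dir, "truth_clicks.csv"),
    counts = file.path(out_dir, "minute_counts.csv"),
    annotations = file.path(out_dir, "annotations.csv"),
    scenario = file.path(out_dir, "scenario.json")
  )
  write_wav(rec$clip, paths$wav)
  utils::write.csv(
    data.frame(center_time_s = clicks$center_time,
               peak_frequency_hz = clicks$peak_frequency,
               snr_db = clicks$snr_db),
    paths$truth, row.names = FALSE)
  utils::write.csv(sim$minutes, paths$counts, row.names = FALSE)
  utils::write.csv(sim$annotations, paths$annotations, row.names = FALSE)
  jsonlite::write_json(unclass(scenario), paths$scenario, auto_unbox = TRUE,
                       digits = NA)
  write_manifest(out_dir, "simulate",
                 list(truth_clicks = nrow(clicks),
                      minutes = nrow(sim$minutes),
                      annotations = nrow(sim$annotations)),
                 config = unclass(scenario))
  invisible(paths)
}

#' Detect stage: run the click detector over a WAV file
#'
#' Executes the detection pipeline in order (high-pass filter, STFT, frame
#' classification, event merging), then derives click trains and
#' per-minute click densities, and writes the three result tables.
#'
#' @param wav_path input WAV.
#' @param model a `click_classifier` or path to one saved with
#'   [save_classifier()].
#' @param out_dir output directory.
#' @param config a [detector_config()]; its STFT geometry must match the
#'   model.
#' @return invisibly, a list with the three tables.
#' @export
run_detect <- function(wav_path, model, out_dir,
                       config = detector_config()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir)
  }
  if (is.character(model)) model <- load_classifier(model)
  clip <- read_wav(wav_path)
  events <- detect_clicks(clip, model, config)
  trains <- segment_trains(events)
  dens <- withCallingHandlers(
    click_density(events, length(clip$samples) / clip$sample_rate),
    warning = function(w) invokeRestart("muffleWarning"))

  utils::write.csv(
    data.frame(time_s = events$time, duration_s = events$duration,
               peak_frequency_hz = events$peak_frequency,
               score = events$score),
    file.path(out_dir, "events.csv"), row.names = FALSE)
  train_tbl <- if (length(trains) > 0) {
    do.call(rbind, lapply(seq_along(trains), function(i) {
      tr <- trains[[i]]
      data.frame(train_id = i, n_clicks = nrow(tr$clicks),
                 start_s = tr$clicks$time[1],
                 end_s = tr$clicks$time[nrow(tr$clicks)],
                 median_ici_ms = stats::median(tr$icis) * 1000)
    }))
  } else {
    data.frame(train_id = integer(0), n_clicks = integer(0),
               start_s = numeric(0), end_s = numeric(0),
               median_ici_ms = numeric(0))
  }
  utils::write.csv(train_tbl, file.path(out_dir, "trains.csv"),
                   row.names = FALSE)
  utils::write.csv(dens, file.path(out_dir, "densities.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "detect",
                 list(events = nrow(events), trains = nrow(train_tbl),
                      densities = nrow(dens)),
                 config = unclass(config), inputs = wav_path)
  invisible(list(events = events, trains = train_tbl, densities = dens))
}

#' Analyze stage: context GLMM over count and annotation tables
#'
#' Reproduces the statistical sequence: design construction with the
#' enrichment split and live-fish exclusion, VIF collinearity screen,
#' Poisson GLMM with offset and date/session random intercepts,
#' overdispersion diagnosis, addition of the observation-level random
#' intercept, AIC selection (with and without the diurnal term), Wald
#' chi-squared tests, and (optionally) Holm-adjusted pairwise contrasts
#' for every multi-level factor.
#'
#' @param counts_csv,annotations_csv input table paths (as written by
#'   [run_simulate()]).
#' @param out_dir output directory.
#' @param contrasts run the pairwise-contrast refits (one GLMM per level
#'   pair; substantially slower).
#' @return invisibly, a list with the design, VIF table, selected fit,
#'   effects table and contrast tables.
#' @export
run_analyze <- function(counts_csv, annotations_csv, out_dir,
                        contrasts = FALSE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir)
  }
  minutes <- utils::read.csv(counts_csv)
  annotations <- utils::read.csv(annotations_csv)
  design <- build_design(minutes, annotations)
  vif_tbl <- vif(design$design)

  base <- fit_poisson_glmm(design, random = c("date", "session"))
  od <- overdispersion_ratio(base)
  random <- if (od$ratio > 1.1) c("date", "session", "observation")
            else c("date", "session")
  candidates <- list(fit_poisson_glmm(design, random = random))
  if ("time_of_day" %in% design$fixed_terms) {
    candidates <- c(candidates, list(fit_poisson_glmm(
      design, fixed_terms = setdiff(design$fixed_terms, "time_of_day"),
      random = random)))
  }
  fit <- aic_select(candidates)
  effects <- wald_test(fit)

  contrast_tbls <- list()
  if (contrasts) {
    for (f in intersect(c("season", "time_of_day", "unusual_event", "visitors"),
                        fit$fixed_terms)) {
      if (nlevels(design$data[[f]]) >= 3) {
        contrast_tbls[[f]] <- pairwise_contrasts(
          design, f, fixed_terms = fit$fixed_terms, random = fit$random)
      }
    }
  }

  utils::write.csv(vif_tbl, file.path(out_dir, "vif.csv"), row.names = FALSE)
  utils::write.csv(effects, file.path(out_dir, "effects.csv"),
                   row.names = FALSE)
  for (f in names(contrast_tbls)) {
    utils::write.csv(contrast_tbls[[f]],
                     file.path(out_dir, paste0("contrasts_", f, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(coefficients = fit$coefficients,
         random_effect_sd = as.list(fit$re_sd),
         logLik = fit$logLik, aic = fit$aic, n_params = fit$n_params,
         n_obs = fit$n_obs, converged = fit$converged,
         candidate_aics = vapply(candidates, `[[`, numeric(1), "aic"),
         overdispersion_before_olre = od,
         live_fish_rows_dropped = design$n_dropped),
    file.path(out_dir, "fit_summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "analyze",
                 list(minutes_analyzed = fit$n_obs,
                      effects = nrow(effects),
                      live_fish_dropped = design$n_dropped),
                 inputs = c(counts_csv, annotations_csv))
  if (!fit$converged) warning("selected model did not converge cleanly")
  invisible(list(design = design, vif = vif_tbl, fit = fit,
                 effects = effects, contrasts = contrast_tbls))
}

#' Run the full simulate / train / detect / analyze pipeline
#'
#' Thin composition of the stage functions with one global seed; writes
#' every stage into subdirectories of `out_dir`. Intended for small demo
#' runs — stage functions are the unit of real work.
#'
#' @param out_dir output directory.
#' @param scenario a [scenario_config()] (its seed drives all stages).
#' @param n_spectra size of the classifier training set.
#' @param audio render settings for [run_simulate()].
#' @param contrasts passed to [run_analyze()].
#' @return invisibly, a list of per-stage results.
#' @export
run_all <- function(out_dir, scenario = scenario_config(),
                    n_spectra = 400,
                    audio = list(duration = 10, sample_rate = 576000,
                                 train_rate_per_min = 20,
                                 snr_db = c(12, 25), noise_level_db = -40,
                                 echo_model = FALSE),
                    contrasts = FALSE) {
  sim_paths <- run_simulate(file.path(out_dir, "simulate"), scenario, audio)
  spectra <- generate_spectra_dataset(n_spectra, 0.5, seed = scenario$seed + 2L)
  spectra <- augment_spectra(spectra, max_db = 3, copies = 1,
                             seed = scenario$seed + 3L)
  model <- train_classifier(spectra, seed = scenario$seed + 4L)
  model_path <- file.path(out_dir, "model.rds")
  save_classifier(model, model_path)
  det <- run_detect(sim_paths$wav, model, file.path(out_dir, "detect"))
  ana <- run_analyze(sim_paths$counts, sim_paths$annotations,
                     file.path(out_dir, "analyze"), contrasts = contrasts)
  invisible(list(simulate = sim_paths, model = model_path, detect = det,
                 analyze = ana))
}
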