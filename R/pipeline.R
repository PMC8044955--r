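# Pipeline orchestration: validated YAML config, staged artifacts, seeded
# reproducibility. The command-line wrapper in inst/cli/fogcast.R is a thin
# shell over run_pipeline().

config_error <- function(fmt, ...) {
  stop(structure(class = c("fogcast_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

missing_artifact <- function(file, producer) {
  stop(structure(class = c("fogcast_missing_artifact", "error", "condition"),
                 list(message = sprintf(
                   "missing artifact '%s'; run mode '%s' first", file, producer),
                   call = NULL)))
}

PIPELINE_SCHEMA <- list(
  seed = "integer",
  log_level = "character",
  simulate = list(
    n_patients = "integer", duration_s = "numeric", fog_schedule = "list",
    params = list(
      sampling_rate_hz = "numeric", n_sensors = "integer",
      n_channels_per_sensor = "integer", step_frequency_hz = "numeric",
      gait_amplitude = "numeric", fog_band_hz = "numeric",
      fog_amplitude = "numeric", prefog_drift = "numeric",
      noise_sd = "numeric", burst_outlier_rate = "numeric",
      prefog_ramp_s = "numeric", seed = "integer"
    )
  ),
  segmentation = list(window_size = "integer", step = "integer",
                      prefog_duration = "integer"),
  design = list(scheme = "character"),
  rf = list(n_estimators = "integer", max_features = "numeric",
            max_depth = "integer", min_samples_split = "integer",
            min_samples_leaf = "integer", seed = "integer"),
  select = list(k_grid = "integer"),
  evaluate = list(horizon_s = "numeric", gap_tolerance_windows = "integer",
                  response = "character")
)

check_schema <- function(x, schema, path = "") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown)) {
    config_error("unknown config key '%s%s'", path, unknown[1])
  }
  for (k in names(x)) {
    spec <- schema[[k]]
    if (is.list(spec) && !identical(k, "fog_schedule")) {
      if (!is.list(x[[k]])) config_error("config key '%s%s' must be a mapping", path, k)
      check_schema(x[[k]], spec, paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with sections `simulate`, `segmentation`, `design`,
#' `rf`, `select`, `evaluate` plus a global `seed`. Unknown keys are rejected
#' with a field-level message; every random stage derives its own seed
#' deterministically from the global seed.
#'
#' @param path YAML file path, or a list already parsed.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) config_error("config file not found: %s", path)
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  check_schema(cfg, PIPELINE_SCHEMA)
  defaults <- list(
    seed = 1L, log_level = "info",
    simulate = list(n_patients = 6L, duration_s = 45,
                    fog_schedule = list(c(15, 3), c(36, 3)),
                    params = list()),
    segmentation = list(window_size = 500L, step = 20L, prefog_duration = 250L),
    design = list(scheme = "l16"),
    rf = list(),
    select = list(k_grid = c(23L, 92L, 231L, 462L, 924L)),
    # kappa is prevalence-corrected: F1's no-skill baseline rises with the
    # preFOG prevalence, which the label-duration factor changes across runs
    evaluate = list(horizon_s = 6, gap_tolerance_windows = 0L, response = "kappa")
  )
  merge_lists <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]]) && k != "fog_schedule") {
        merge_lists(a[[k]], b[[k]])
      } else b[[k]]
    }
    a
  }
  cfg <- merge_lists(defaults, cfg)
  if (!cfg$design$scheme %in% c("l16", "full")) {
    config_error("design.scheme must be 'l16' or 'full'")
  }
  if (!cfg$evaluate$response %in% c("F1", "kappa")) {
    config_error("evaluate.response must be 'F1' or 'kappa'")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

cfg_sim_params <- function(cfg, seed) {
  args <- cfg$simulate$params
  args$seed <- derive_seed(seed, "simulate")
  do.call(gait_sim_params, args)
}

cfg_rf_params <- function(cfg, seed) {
  args <- cfg$rf
  args$seed <- derive_seed(seed, "train")
  do.call(rf_params, args)
}

read_cohort <- function(out_dir) {
  cj <- file.path(out_dir, "cohort.json")
  if (!file.exists(cj)) missing_artifact("cohort.json", "simulate")
  ids <- jsonlite::read_json(cj, simplifyVector = TRUE)$patients
  recs <- list(); anns <- list()
  for (pid in ids) {
    rr <- read_recording(out_dir, pid)
    recs[[pid]] <- rr$recording
    anns[[pid]] <- rr$annotation
  }
  list(recordings = recs, annotations = anns)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the pipeline
#'
#' Stages: `simulate` (write the synthetic cohort), `preprocess` (windows
#' index at the configured segmentation), `extract` (feature CSV), `run-oed`
#' (design + response tables), `analyze` (effects + LogWorth), `train`
#' (LOPO fold metrics at the configured segmentation), `select` (top-K
#' feature selection), `evaluate` (episode metrics), and `all` (simulate,
#' OED over the 16-run design, effects analysis, best-level selection,
#' retrain at the optimum, episode evaluation). Artifacts carry a
#' `manifest.json` with the config hash and seed; rerunning with the same
#' config and seed reproduces them byte for byte.
#'
#' @param cfg a [read_pipeline_config()] result (or a path / list accepted by
#'   it).
#' @param mode one of simulate, preprocess, extract, run-oed, analyze, train,
#'   select, evaluate, all.
#' @param out_dir artifact directory.
#' @param seed optional override of the config's global seed.
#' @param verbose print stage progress.
#' @return invisibly, a named list of artifact paths (plus key results).
#' @export
run_pipeline <- function(cfg, mode = c("all", "simulate", "preprocess",
                                       "extract", "run-oed", "analyze",
                                       "train", "select", "evaluate"),
                         out_dir = "fogcast_out", seed = NULL,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- list()

  do_simulate <- function() {
    p <- cfg_sim_params(cfg, cfg$seed)
    say("simulating %d patients, %gs each", cfg$simulate$n_patients,
        cfg$simulate$duration_s)
    cohort <- simulate_cohort(cfg$simulate$n_patients, cfg$simulate$duration_s,
                              cfg$simulate$fog_schedule, p,
                              seed = derive_seed(cfg$seed, "cohort"))
    for (pid in names(cohort$recordings)) {
      write_recording(cohort$recordings[[pid]], cohort$annotations[[pid]], out_dir)
    }
    write_json_artifact(list(patients = names(cohort$recordings)),
                        file.path(out_dir, "cohort.json"))
    cohort
  }

  seg_from_cfg <- function() {
    do.call(segmentation_params, cfg$segmentation)
  }

  if (mode == "simulate") {
    do_simulate()
    artifacts$cohort <- file.path(out_dir, "cohort.json")
  } else if (mode == "preprocess") {
    cohort <- read_cohort(out_dir)
    sp <- seg_from_cfg()
    wins <- do.call(rbind, lapply(names(cohort$recordings), function(pid) {
      rec <- preprocess_recording(cohort$recordings[[pid]])
      segment_and_label(rec, cohort$annotations[[pid]], sp)$windows
    }))
    data.table::fwrite(wins, file.path(out_dir, "windows.csv"))
    artifacts$windows <- file.path(out_dir, "windows.csv")
  } else if (mode == "extract") {
    cohort <- read_cohort(out_dir)
    sp <- seg_from_cfg()
    wsets <- lapply(names(cohort$recordings), function(pid) {
      segment_and_label(preprocess_recording(cohort$recordings[[pid]]),
                        cohort$annotations[[pid]], sp)
    })
    fm <- extract_matrix(wsets)
    out <- cbind(fm$windows, as.data.frame(signif(fm$X, 9)))
    data.table::fwrite(out, file.path(out_dir, "features.csv"))
    artifacts$features <- file.path(out_dir, "features.csv")
  } else if (mode == "run-oed") {
    cohort <- read_cohort(out_dir)
    d <- if (cfg$design$scheme == "l16") build_l16_4_3() else full_factorial()
    data.table::fwrite(d$runs, file.path(out_dir, "design.csv"))
    resp <- run_design(d, cohort$recordings, cohort$annotations,
                       cfg_rf_params(cfg, cfg$seed),
                       seeds = derive_seed(cfg$seed, "oed"), verbose = verbose)
    data.table::fwrite(as.data.frame(resp), file.path(out_dir, "responses.csv"))
    artifacts$design <- file.path(out_dir, "design.csv")
    artifacts$responses <- file.path(out_dir, "responses.csv")
  } else if (mode == "analyze") {
    dp <- file.path(out_dir, "design.csv")
    rp <- file.path(out_dir, "responses.csv")
    if (!file.exists(dp) || !file.exists(rp)) missing_artifact("responses.csv", "run-oed")
    d <- as_design_table(data.table::fread(dp, data.table = FALSE),
                         cfg$design$scheme)
    resp <- data.table::fread(rp, data.table = FALSE)
    eff <- effects_analysis(d, resp, cfg$evaluate$response,
                            interactions = list(c("window_size", "prefog_duration")))
    data.table::fwrite(as.data.frame(eff), file.path(out_dir, "effects.csv"))
    write_json_artifact(
      list(response = attr(eff, "response"), coding = attr(eff, "coding"),
           terms = as.data.frame(eff),
           level_means = lapply(attr(eff, "level_means"), as.list),
           best = unclass(select_best(eff))),
      file.path(out_dir, "effects.json"))
    artifacts$effects <- file.path(out_dir, "effects.json")
  } else if (mode == "train") {
    cohort <- read_cohort(out_dir)
    sp <- seg_from_cfg()
    score <- end_to_end_eval(cohort$recordings, cohort$annotations, sp,
                             cfg_rf_params(cfg, cfg$seed),
                             cfg$evaluate$horizon_s,
                             cfg$evaluate$gap_tolerance_windows)
    wm <- attr(score, "window_metrics")
    write_json_artifact(
      list(params = cfg$segmentation, rf = cfg$rf, seed = cfg$seed,
           F1 = wm$F1, kappa = wm$kappa, counts = as.list(wm$counts)),
      file.path(out_dir, "model_manifest.json"))
    artifacts$model <- file.path(out_dir, "model_manifest.json")
  } else if (mode == "select") {
    cohort <- read_cohort(out_dir)
    sp <- seg_from_cfg()
    wsets <- lapply(names(cohort$recordings), function(pid) {
      segment_and_label(preprocess_recording(cohort$recordings[[pid]]),
                        cohort$annotations[[pid]], sp)
    })
    fm <- extract_matrix(wsets)
    k_grid <- pmin(cfg$select$k_grid, ncol(fm$X))
    sel <- topk_select(fm, cfg_rf_params(cfg, cfg$seed), unique(k_grid))
    write_json_artifact(
      list(k = sel$k, F1 = sel$F1, kappa = sel$kappa,
           base_features = sel$base_feature_report, selected = sel$selected),
      file.path(out_dir, "selection.json"))
    artifacts$selection <- file.path(out_dir, "selection.json")
  } else if (mode == "evaluate") {
    cohort <- read_cohort(out_dir)
    sp <- seg_from_cfg()
    score <- end_to_end_eval(cohort$recordings, cohort$annotations, sp,
                             cfg_rf_params(cfg, cfg$seed),
                             cfg$evaluate$horizon_s,
                             cfg$evaluate$gap_tolerance_windows)
    write_json_artifact(episode_score_json(score),
                        file.path(out_dir, "episode_score.json"))
    artifacts$episode_score <- file.path(out_dir, "episode_score.json")
  } else if (mode == "all") {
    cohort <- do_simulate()
    d <- if (cfg$design$scheme == "l16") build_l16_4_3() else full_factorial()
    data.table::fwrite(d$runs, file.path(out_dir, "design.csv"))
    say("running %d-run design", nrow(d$runs))
    resp <- run_design(d, cohort$recordings, cohort$annotations,
                       cfg_rf_params(cfg, cfg$seed),
                       seeds = derive_seed(cfg$seed, "oed"), verbose = verbose)
    data.table::fwrite(as.data.frame(resp), file.path(out_dir, "responses.csv"))
    eff <- effects_analysis(d, resp, cfg$evaluate$response,
                            interactions = list(c("window_size", "prefog_duration")))
    data.table::fwrite(as.data.frame(eff), file.path(out_dir, "effects.csv"))
    best <- select_best(eff)
    write_json_artifact(
      list(response = attr(eff, "response"), coding = attr(eff, "coding"),
           terms = as.data.frame(eff),
           level_means = lapply(attr(eff, "level_means"), as.list),
           best = unclass(best)),
      file.path(out_dir, "effects.json"))
    say("best parameters: window %d, step %d, prefog %d", best$window_size,
        best$step, best$prefog_duration)
    # match episodes with the lead implied by the selected parameters
    fs <- cohort$recordings[[1]]$sampling_rate_hz
    score <- end_to_end_eval(cohort$recordings, cohort$annotations, best,
                             cfg_rf_params(cfg, cfg$seed),
                             lead_horizon_s(best, fs),
                             cfg$evaluate$gap_tolerance_windows)
    write_json_artifact(episode_score_json(score),
                        file.path(out_dir, "episode_score.json"))
    artifacts <- list(
      cohort = file.path(out_dir, "cohort.json"),
      design = file.path(out_dir, "design.csv"),
      responses = file.path(out_dir, "responses.csv"),
      effects = file.path(out_dir, "effects.json"),
      episode_score = file.path(out_dir, "episode_score.json"))
    artifacts$best <- best
    artifacts$episode_score_value <- score
  }

  manifest <- list(
    mode = mode, seed = cfg$seed,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("fogcast")),
    artifacts = artifacts[vapply(artifacts, is.character, logical(1))]
  )
  write_json_artifact(manifest, file.path(out_dir, "manifest.json"))
  invisible(artifacts)
}

episode_score_json <- function(score) {
  wm <- attr(score, "window_metrics")
  list(
    hit_rate = score$hit_rate,
    false_positive_rate = as.numeric(score$false_positive_rate),
    mpt_s = score$mpt_s,
    n_episodes = score$n_episodes, n_hits = score$n_hits,
    n_alarms = score$n_alarms, n_false_alarms = score$n_false_alarms,
    horizon_s = score$horizon_s,
    window_F1 = if (!is.null(wm)) wm$F1 else NULL,
    window_kappa = if (!is.null(wm)) wm$kappa else NULL
  )
}

# Stable hash of the config: serialized canonical text, summed byte rolling
# hash (no external digest dependency).
config_hash <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
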