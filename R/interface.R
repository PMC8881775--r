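#' Pipeline orchestration
#'
#' A single configuration drives every stage; each command reads its
#' upstream artifacts from the output directory and writes versioned
#' tables stamped with the configuration hash and seed, so a rerun with
#' the same configuration reproduces every table byte for byte.
#'
#' @name interface
NULL

RUN_CONFIG_KEYS <- c("out_dir", "seed", "simulation", "render", "alpha",
                     "n_splits", "min_responses", "levels", "feature_sets",
                     "emotions", "report")

#' Build and validate a run configuration
#'
#' @param config named list (or path to a YAML file when the yaml package
#'   is installed) with keys: `out_dir`, `seed`, `simulation` (arguments
#'   for [simulation_config()]), `render` ("none"/"full"), `alpha`,
#'   `n_splits`, `min_responses`, `levels`, `feature_sets`, `emotions`,
#'   `report`. Unknown keys are rejected.
#' @return validated run-config list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stopf("config needs out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  config$render <- config$render %||% "none"
  config$alpha <- config$alpha %||% 0.05
  config$n_splits <- config$n_splits %||% 50L
  config$min_responses <- config$min_responses %||% 30L
  config$levels <- config$levels %||% c("momentary", "trait")
  config$feature_sets <- config$feature_sets %||%
    c("speech_content", "speech_form", "writing_content", "writing_form")
  config$emotions <- config$emotions %||% EMOTIONS
  sim_args <- config$simulation %||% list()
  sim_args$rng_seed <- sim_args$rng_seed %||% config$seed
  config$sim <- do.call(simulation_config, sim_args)
  config
}

write_stamped_csv <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# emolang config_hash=%s seed=%d",
                     config_hash(config$sim), config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

read_stamped_csv <- function(path, producer) {
  if (!file.exists(path))
    stopf("missing %s -- run the '%s' command first", path, producer)
  utils::read.csv(path, comment.char = "#")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run one pipeline command
#'
#' Commands: `simulate` (generate the synthetic study), `extract`
#' (feature extraction from rendered artifacts, or the ground-truth
#' passthrough for feature-level renders), `assemble` (linkage,
#' inclusion, standardization, trait aggregation), `associate`
#' (association tables with Holm correction), `predict` (resampled
#' predictive R²), `report` (summary JSON), `all` (the whole chain).
#' Each command requires its upstream artifacts and errors with the name
#' of the producing command when they are missing.
#'
#' @param command one of the above.
#' @param config a [run_config()] list (or raw list/path accepted by it).
#' @return invisibly, the paths written.
#' @export
run_command <- function(command = c("simulate", "extract", "assemble",
                                    "associate", "predict", "report", "all"),
                        config) {
  command <- match.arg(command)
  config <- if (is.list(config) && !is.null(config$sim)) config
            else run_config(config)
  if (command == "all") {
    paths <- c(run_command("simulate", config), run_command("extract", config),
               run_command("assemble", config),
               run_command("associate", config),
               run_command("predict", config), run_command("report", config))
    return(invisible(paths))
  }
  switch(command,
         simulate = cmd_simulate(config),
         extract = cmd_extract(config),
         assemble = cmd_assemble(config),
         associate = cmd_associate(config),
         predict = cmd_predict(config),
         report = cmd_report(config))
}

cmd_simulate <- function(config) {
  d <- stage_dir(config, "simulate")
  study <- simulate_study(config$sim, render = config$render,
                          out_dir = if (config$render == "full")
                            file.path(d, "artifacts") else NULL)
  paths <- c(
    write_stamped_csv(study$surveys, file.path(d, "surveys.csv"), config),
    write_stamped_csv(study$features, file.path(d, "features.csv"), config),
    write_stamped_csv(study$dass, file.path(d, "dass.csv"), config),
    write_stamped_csv(study$profiles, file.path(d, "profiles.csv"), config))
  if (!is.null(study$keystrokes))
    paths <- c(paths, write_stamped_csv(study$keystrokes,
                                        file.path(d, "keystrokes.csv"), config))
  if (!is.null(study$artifacts))
    paths <- c(paths, write_stamped_csv(study$artifacts,
                                        file.path(d, "manifest.csv"), config))
  jsonlite::write_json(list(config_hash = config_hash(config$sim),
                            seed = config$seed),
                       file.path(d, "ground_truth_meta.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}

read_study <- function(config, features_file = "features.csv") {
  d <- file.path(config$out_dir, "simulate")
  surveys <- read_stamped_csv(file.path(d, "surveys.csv"), "simulate")
  features <- read_stamped_csv(file.path(d, features_file),
                               if (features_file == "features.csv")
                                 "simulate" else "extract")
  dass <- read_stamped_csv(file.path(d, "dass.csv"), "simulate")
  list(surveys = surveys, features = features, dass = dass)
}

cmd_extract <- function(config) {
  d <- stage_dir(config, "extract")
  sim_d <- file.path(config$out_dir, "simulate")
  if (config$render == "full") {
    study <- read_study(config)
    study$artifacts <- read_stamped_csv(file.path(sim_d, "manifest.csv"),
                                        "simulate")
    ksp <- file.path(sim_d, "keystrokes.csv")
    study$keystrokes <- if (file.exists(ksp))
      read_stamped_csv(ksp, "simulate") else NULL
    feats <- extract_study_features(study)
  } else {
    # feature-level render: the ground truth is the extracted stream
    feats <- read_study(config)$features
  }
  invisible(write_stamped_csv(feats, file.path(d, "extracted_features.csv"),
                              config))
}

cmd_assemble <- function(config) {
  d <- stage_dir(config, "assemble")
  study <- read_study(config)
  feats <- read_stamped_csv(file.path(config$out_dir, "extract",
                                      "extracted_features.csv"), "extract")
  paths <- character(0)
  for (stream in c("voice", "keyboard")) {
    ds <- assemble_analysis(study, stream,
                            min_responses = config$min_responses,
                            features = feats)
    paths <- c(paths,
               write_stamped_csv(ds$momentary,
                                 file.path(d, paste0("momentary_", stream, ".csv")),
                                 config),
               write_stamped_csv(ds$trait,
                                 file.path(d, paste0("trait_", stream, ".csv")),
                                 config))
    jsonlite::write_json(list(accounting = ds$accounting,
                              retained = ds$retained,
                              n_linked = ds$n_linked),
                         file.path(d, paste0("accounting_", stream, ".json")))
  }
  invisible(paths)
}

stream_of_set <- function(set_name) {
  if (grepl("^speech", set_name)) "voice"
  else if (grepl("^writing", set_name)) "keyboard" else "all"
}

cmd_associate <- function(config) {
  d <- stage_dir(config, "associate")
  a <- file.path(config$out_dir, "assemble")
  fs <- feature_sets()
  paths <- character(0)
  for (stream in c("voice", "keyboard")) {
    fams <- fs[vapply(names(fs), function(s) stream_of_set(s) == stream,
                      logical(1))]
    fams <- fams[!grepl("combined", names(fams))]
    for (level in config$levels) {
      data <- read_stamped_csv(file.path(a, paste0(level, "_", stream, ".csv")),
                               "assemble")
      tab <- association_tables(list(momentary = data, trait = data), fams,
                                level = level, alpha = config$alpha)
      paths <- c(paths, write_stamped_csv(
        tab, file.path(d, paste0("associations_", level, "_", stream, ".csv")),
        config))
    }
  }
  invisible(paths)
}

cmd_predict <- function(config) {
  d <- stage_dir(config, "predict")
  a <- file.path(config$out_dir, "assemble")
  s <- file.path(config$out_dir, "associate")
  fs <- feature_sets()
  summary_rows <- list(); split_rows <- list()
  for (set_name in config$feature_sets) {
    stream <- stream_of_set(set_name)
    streams <- if (stream == "all") c("voice") else stream
    for (level in config$levels) {
      data <- read_stamped_csv(file.path(a, paste0(level, "_", streams[1], ".csv")),
                               "assemble")
      assoc <- read_stamped_csv(file.path(s, paste0("associations_", level, "_",
                                                    streams[1], ".csv")),
                                "associate")
      feats <- intersect(fs[[set_name]], names(data))
      for (emotion in config$emotions) {
        pr <- resample_splits(data, emotion, feats, assoc, level = level,
                              n_splits = config$n_splits,
                              seed = derive_seed(config$seed,
                                                 match(set_name, names(fs)),
                                                 match(emotion, EMOTIONS)),
                              set_name = set_name)
        summary_rows[[length(summary_rows) + 1]] <-
          data.frame(level = level, emotion = emotion, set_name = set_name,
                     mean_r2 = pr$mean_r2, sd_r2 = pr$sd_r2,
                     n_failed = pr$n_failed, unreliable = pr$unreliable)
        sp <- pr$splits
        sp$level <- level; sp$emotion <- emotion; sp$set_name <- set_name
        split_rows[[length(split_rows) + 1]] <- sp
      }
    }
  }
  invisible(c(
    write_stamped_csv(do.call(rbind, summary_rows),
                      file.path(d, "predictive_summary.csv"), config),
    write_stamped_csv(do.call(rbind, split_rows),
                      file.path(d, "predictive_splits.csv"), config)))
}

cmd_report <- function(config) {
  d <- stage_dir(config, "report")
  surveys <- read_stamped_csv(file.path(config$out_dir, "simulate",
                                        "surveys.csv"), "simulate")
  pred <- read_stamped_csv(file.path(config$out_dir, "predict",
                                     "predictive_summary.csv"), "predict")
  n_per <- table(surveys$participant_id)
  sched <- config$sim$n_days * config$sim$beeps_per_day
  rep <- list(config_hash = config_hash(config$sim),
              seed = config$seed,
              participants = length(n_per),
              scheduled_beeps = sched,
              mean_compliance = mean(n_per / sched),
              predictive = pred)
  path <- file.path(d, "report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
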