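#' Default run configuration
#'
#' Every pipeline parameter with its default, including the named presets
#' used across the assays: vesicle frame interval 2 s, TIRF frame interval
#' 0.041 s, pause threshold 0.1 um/s, moving-motor thresholds
#' 0.12 um/s / 0.2 um / 0.9 s, and Golgi large-object presets 4.11 um^2
#' (siRNA) and 2.74 um^2 (nocodazole).
#'
#' @return A named list; round-trips losslessly through
#'   [write_config()] / [read_config()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "kinemetry_run",
    stages = c("simulate", "motion"),
    simulate = list(
      n_tracks = 50L,
      confined_fraction = 0.5,
      frame_interval = 2,
      n_frames = 71L,
      diffusion_coefficient = 0.05,
      confinement_radius = 0.5,
      speed = 0.5,
      reversal_rate = 0.05,
      pause_rate = 0.05,
      pause_duration_mean = 4,
      localization_noise_sd = 0.02
    ),
    motion = list(
      alpha_confined = 0.7,
      alpha_linear = 1.3,
      min_points = 20L,
      pause_speed_threshold = 0.1
    ),
    presets = list(
      frame_interval_vesicle_s = 2,
      frame_interval_tirf_s = 0.041,
      pause_speed_threshold_um_s = 0.1,
      moving_speed_min_um_s = 0.12,
      moving_distance_min_um = 0.2,
      moving_duration_min_s = 0.9,
      golgi_area_threshold_sirna_um2 = 4.11,
      golgi_area_threshold_nocodazole_um2 = 2.74
    )
  )
}

#' Read / write a run configuration
#'
#' YAML serialization of the configuration list. Unknown top-level keys are
#' rejected by name so typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return `read_config()`: the merged configuration (defaults overridden by
#'   the file's values).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user, prefix = "") {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste0(prefix, unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(prefix, k, "$"))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Run the simulation/analysis pipeline
#'
#' Executes the requested stages in order and writes CSV outputs plus a
#' machine-readable manifest (parameters, seed, package version, per-stage
#' counts) into `config$output_dir`. Identical configuration and seed give
#' byte-identical outputs. A stage failure aborts with the stage name;
#' outputs of earlier stages are preserved.
#'
#' @param config configuration list as from [default_config()] or
#'   [read_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- merge_config(default_config(), config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("kinemetry")),
                   seed = config$seed, config = config, stages = list())
  results <- list()
  for (stage in config$stages) {
    res <- tryCatch(
      switch(stage,
        simulate = stage_simulate(config),
        motion = stage_motion(config, results),
        stop(sprintf("unknown stage '%s'", stage), call. = FALSE)),
      error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE))
    results[[stage]] <- res
    manifest$stages[[stage]] <- res$counts
  }
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yml"))
  invisible(list(results = results, manifest = manifest))
}

stage_simulate <- function(config) {
  s <- config$simulate
  n_conf <- round(s$n_tracks * s$confined_fraction)
  base <- function(mode) track_sim_params(
    mode = mode, diffusion_coefficient = s$diffusion_coefficient,
    confinement_radius = s$confinement_radius, speed = s$speed,
    reversal_rate = s$reversal_rate, pause_rate = s$pause_rate,
    pause_duration_mean = s$pause_duration_mean,
    frame_interval = s$frame_interval, n_frames = s$n_frames,
    localization_noise_sd = s$localization_noise_sd)
  tracks <- c(
    simulate_cohort(n_conf, base("confined"), seed = config$seed),
    simulate_cohort(s$n_tracks - n_conf, base("directed"),
                    seed = config$seed + 1L))
  for (i in seq_along(tracks)) attr(tracks[[i]], "track_id") <- as.character(i)
  truth <- data.frame(track_id = as.character(seq_along(tracks)),
                      true_class = rep(c("confined", "directed"),
                                       c(n_conf, s$n_tracks - n_conf)))
  write_tracks(tracks, file.path(config$output_dir, "tracks.csv"))
  utils::write.csv(truth, file.path(config$output_dir, "tracks_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  list(tracks = tracks, truth = truth,
       counts = list(n_tracks = length(tracks), n_confined_truth = n_conf))
}

stage_motion <- function(config, results) {
  m <- config$motion
  tracks <- if (!is.null(results$simulate)) results$simulate$tracks
    else read_tracks(file.path(config$output_dir, "tracks.csv"),
                     config$simulate$frame_interval)
  rep <- motion_report(tracks, alpha_confined = m$alpha_confined,
                       alpha_linear = m$alpha_linear,
                       min_points = m$min_points,
                       pause_speed_threshold = m$pause_speed_threshold)
  num <- vapply(rep, is.numeric, logical(1))
  rep[num] <- lapply(rep[num], round, digits = 6)
  utils::write.csv(rep, file.path(config$output_dir, "motion_report.csv"),
                   row.names = FALSE, quote = FALSE)
  counts <- as.list(table(rep$class))
  list(report = rep, counts = counts)
}
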