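#' Default run configuration
#'
#' The YAML-serializable configuration covering every tunable of the
#' pipeline. Sections: `synapse` (kinetics), `stimulus` (theta/burst/DBS),
#' `cohort` (pathology generator), `therapy`, `engine`, `trial`, and
#' `weights` (per-class base synaptic weights as `[w_e, w_m]`).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    master_seed = 1L,
    synapse = synapse_params(),
    stimulus = list(theta_hz = 8, burst_size = 5L, burst_hz = 100,
                    dbs_hz = 40),
    cohort = list(n_networks = 100L, prop_moderate = 0.5,
                  severity_moderate = c(0.30, 0.55),
                  severity_severe = c(0.55, 0.85),
                  levels_moderate = c(56.7, 63),
                  levels_severe = c(63, 135)),
    therapy = list(memantine_level = 3L, memantine_concentration = 10),
    engine = engine_params(),
    trial = list(n_patients = 20L, mode = "within", ratio = c(1, 1, 1, 1)),
    weights = default_weights()
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration key ", full, " must be a mapping",
             call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$stimulus$theta_hz < 4 || cfg$stimulus$theta_hz > 12) {
    stop("stimulus.theta_hz: theta frequency must lie in [4, 12] Hz",
         call. = FALSE)
  }
  if (cfg$stimulus$dbs_hz < 40) {
    stop("stimulus.dbs_hz: DBS frequency must be at least 40 Hz",
         call. = FALSE)
  }
  if (!cfg$therapy$memantine_level %in% 0:3) {
    stop("therapy.memantine_level: must be an integer in 0..3",
         call. = FALSE)
  }
  bad <- setdiff(unlist(cfg$cohort[c("levels_moderate", "levels_severe")]),
                 EXCITOTOXICITY_LEVELS)
  if (length(bad)) {
    stop("cohort.levels_*: excitotoxicity levels must be drawn from ",
         paste(EXCITOTOXICITY_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (!cfg$trial$mode %in% c("within", "between")) {
    stop("trial.mode: must be 'within' or 'between'", call. = FALSE)
  }
  do.call(engine_params, cfg$engine)
  do.call(synapse_params, cfg$synapse)
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are rejected with an
#' error naming the offending key; out-of-range values are rejected with
#' an error naming the key. An empty file yields the all-defaults
#' configuration.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build a trial design from a configuration
#'
#' @param cfg a configuration list from [default_config()] or
#'   [load_config()].
#' @param master_seed optional override of `cfg$master_seed`.
#' @return A [trial_design()].
#' @export
config_to_design <- function(cfg = default_config(), master_seed = NULL) {
  validate_config(cfg)
  seed <- if (is.null(master_seed)) cfg$master_seed else master_seed
  trial_design(
    master_seed = seed,
    n_patients = cfg$trial$n_patients,
    mode = cfg$trial$mode,
    ratio = cfg$trial$ratio,
    memantine_level = cfg$therapy$memantine_level,
    dbs_frequency = cfg$stimulus$dbs_hz,
    cohort = cohort_spec(n_networks = cfg$cohort$n_networks,
                         prop_moderate = cfg$cohort$prop_moderate,
                         severity_moderate = cfg$cohort$severity_moderate,
                         severity_severe = cfg$cohort$severity_severe,
                         levels_moderate = cfg$cohort$levels_moderate,
                         levels_severe = cfg$cohort$levels_severe),
    weights = cfg$weights,
    engine = do.call(engine_params, cfg$engine),
    theta_frequency = cfg$stimulus$theta_hz,
    burst_size = cfg$stimulus$burst_size,
    intra_burst_frequency = cfg$stimulus$burst_hz
  )
}

#' Write trial outputs to a directory
#'
#' Writes the endpoint table and sampled-patient manifest as CSV, the
#' statistical report as JSON, spike-train CSV for the control run, and a
#' provenance record (effective configuration echo, master seed, package
#' version).
#'
#' @param trial the result of [run_trial()].
#' @param out_dir output directory (created if missing).
#' @param cfg optional configuration list echoed alongside the outputs.
#' @return `out_dir`, invisibly.
#' @export
write_trial_outputs <- function(trial, out_dir, cfg = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$endpoints,
                   file.path(out_dir, "endpoints.csv"), row.names = FALSE)
  utils::write.csv(trial$manifest,
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  spikes <- trial$control_result$spike_trains
  spikes <- spikes[order(spikes$cell_id, spikes$t_ms), , drop = FALSE]
  utils::write.csv(spikes, file.path(out_dir, "control_spikes.csv"),
                   row.names = FALSE)
  rep <- trial$report
  jsonlite::write_json(
    list(summaries = rep$summaries, anova = rep$anova, tukey = rep$tukey,
         alpha = rep$alpha, meta = trial$meta),
    file.path(out_dir, "trial_result.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(cfg)) save_config(cfg, file.path(out_dir, "config.yaml"))
  prov <- list(master_seed = trial$meta$master_seed,
               package_version =
                 as.character(utils::packageVersion("hippotrial")),
               created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Export a stimulus program's events as CSV
#'
#' @param program a `stimulus_program`.
#' @param path output CSV path (columns `line_id`, `t_ms`).
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(program, path) {
  utils::write.csv(program$events, path, row.names = FALSE)
  invisible(path)
}

#' Export a network's connection table as CSV
#'
#' @param network a `network_spec`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connections_csv <- function(network, path) {
  con <- network$connections[, c("source", "target", "target_comp",
                                 "kind", "class", "enabled")]
  utils::write.csv(con, path, row.names = FALSE)
  invisible(path)
}
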