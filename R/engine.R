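#' Engine parameters
#'
#' @param duration_ms simulation duration, ms; should be a whole number of
#'   theta cycles (default 2000 ms = 16 cycles at 8 Hz).
#' @param dt_ms integration/synapse time step, ms.
#' @param transient_ms initial transient discarded before spike counting
#'   (default one 8 Hz theta cycle).
#' @param noise_sd zero-mean somatic membrane noise SD, mV per step.
#' @param drive_gain conversion from synaptic depolarization (S - ReP, mV)
#'   to injected compartment current, mV/ms per mV.
#' @param substeps Euler substeps per dt.
#' @return Named list of engine constants.
#' @export
engine_params <- function(duration_ms = 2000, dt_ms = 1, transient_ms = 125,
                          noise_sd = 0.3, drive_gain = 2.5, substeps = 5L) {
  stopifnot(duration_ms > 0, dt_ms > 0, transient_ms >= 0,
            transient_ms < duration_ms, noise_sd >= 0, drive_gain > 0)
  list(duration_ms = duration_ms, dt_ms = dt_ms, transient_ms = transient_ms,
       noise_sd = noise_sd, drive_gain = drive_gain,
       substeps = as.integer(substeps))
}

ALL_LINES <- function() c(EC2_LINES, EC3_LINES, SEPTAL_LINES)

#' Run one network simulation
#'
#' Simulates `network` under `program` and returns the spike trains plus
#' raw regional spike counts (principal cells only: granule cells for DG,
#' pyramidal cells for CA3/CA1), counted after the initial transient.
#' Deterministic given `(network, program, seed)`.
#'
#' @param network a `network_spec`.
#' @param program a `stimulus_program` with matching `dt`.
#' @param seed integer seed for the membrane noise.
#' @param engine an [engine_params()] list.
#' @param synapse a [synapse_params()] list.
#' @return A `simulation_result`: list with `spike_trains` (data.frame
#'   `cell_id`, `t_ms`), `region_counts`, `normalized_counts` (NA until
#'   [normalize_counts()]), and `meta`.
#' @export
run_simulation <- function(network, program, seed = 1L,
                           engine = engine_params(),
                           synapse = synapse_params()) {
  stopifnot(inherits(network, "network_spec"),
            inherits(program, "stimulus_program"))
  if (abs(program$dt - engine$dt_ms) > 1e-12) {
    stop("stimulus program dt does not match engine dt")
  }
  duration <- engine$duration_ms
  cycle <- 1000 / program$theta_frequency
  if (abs(duration / cycle - round(duration / cycle)) > 1e-9) {
    stop("duration must be a whole number of theta cycles")
  }
  if (duration > program$duration) {
    stop("stimulus program shorter than the simulation duration")
  }
  n_steps <- as.integer(round(duration / engine$dt_ms))

  cells <- network$cells
  n_neur <- nrow(cells)
  cell_idx <- stats::setNames(seq_len(n_neur), cells$cell_id)
  lines <- ALL_LINES()
  line_idx <- stats::setNames(seq_along(lines), lines)

  ext <- matrix(0L, nrow = length(lines), ncol = n_steps)
  ev <- program$events
  ev <- ev[ev$t_ms < duration, , drop = FALSE]
  if (nrow(ev)) {
    ext[cbind(line_idx[ev$line_id],
              as.integer(round(ev$t_ms / engine$dt_ms)) + 1L)] <- 1L
  }

  con <- network$connections
  src_kind <- ifelse(con$source_kind == "external", 0L, 1L)
  src_idx <- ifelse(src_kind == 0L, line_idx[con$source] - 1L,
                    cell_idx[con$source] - 1L)
  conn_i <- cbind(src_kind, as.integer(src_idx),
                  as.integer(cell_idx[con$target] - 1L),
                  as.integer(con$target_comp - 1L),
                  ifelse(con$kind == "inhibitory", 1L, 0L),
                  as.integer(con$enabled))
  power <- ifelse(con$excitotoxic, con$power_b, con$power_a)
  conn_d <- cbind(con$w_e, con$w_m, power, con$ca_mem, con$clog)

  set.seed(seed)
  noise <- matrix(stats::rnorm(n_neur * n_steps, 0, engine$noise_sd),
                  nrow = n_neur)

  np <- network$neuron
  pars <- list(n_steps = n_steps, dt = engine$dt_ms,
               substeps = engine$substeps, axial = np$axial,
               rest_potential = np$rest_potential,
               spike_threshold = np$spike_threshold,
               drive_gain = engine$drive_gain, tau_dend = np$tau_dend,
               register_length = synapse$register_length,
               tau_ampa = synapse$tau_ampa, tau_nmda = synapse$tau_nmda,
               tau_gaba = synapse$tau_gaba,
               ltp_duration = synapse$ltp_duration,
               ltp_gain = synapse$ltp_gain)

  res <- engine_run(conn_i, conn_d, ext, noise, cells$tau_m,
                    cells$refractory, pars)
  spikes <- data.frame(cell_id = cells$cell_id[res$neuron],
                       t_ms = res$step * engine$dt_ms,
                       stringsAsFactors = FALSE)
  spikes <- spikes[order(cell_idx[spikes$cell_id], spikes$t_ms), ,
                   drop = FALSE]
  rownames(spikes) <- NULL

  counted <- spikes[spikes$t_ms >= engine$transient_ms, , drop = FALSE]
  counts <- vapply(c("DG", "CA3", "CA1"), function(r) {
    pc <- cells$cell_id[cells$region == r & cells$principal]
    sum(counted$cell_id %in% pc)
  }, integer(1))

  structure(list(
    spike_trains = spikes,
    region_counts = counts,
    normalized_counts = c(DG = NA_real_, CA3 = NA_real_, CA1 = NA_real_),
    meta = list(label = network$label, severity = network$severity,
                excitotoxicity_level = network$excitotoxicity_level,
                dbs = !is.null(program$dbs), seed = seed,
                duration_ms = duration, dt_ms = engine$dt_ms,
                transient_ms = engine$transient_ms)
  ), class = "simulation_result")
}

#' Normalize regional spike counts against the control run
#'
#' The trial endpoints are spike counts relative to the pathology-free
#' control network under the matched (non-DBS) stimulus: a value of 1
#' means control-level output, values above 1 are possible under DBS
#' because the stimulation adds input beyond the control program.
#'
#' @param result a `simulation_result`.
#' @param control_result the control network's `simulation_result`.
#' @return `result` with `normalized_counts` filled.
#' @export
normalize_counts <- function(result, control_result) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(control_result, "simulation_result"))
  ref <- control_result$region_counts
  if (any(ref == 0)) {
    stop("control region count of zero: normalization undefined in region(s) ",
         paste(names(ref)[ref == 0], collapse = ", "))
  }
  result$normalized_counts <- result$region_counts / ref
  result
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$meta$label,
      if (isTRUE(x$meta$dbs)) "[DBS]", "\n")
  cat("  raw counts: ", paste(names(x$region_counts), x$region_counts,
                              sep = "=", collapse = "  "), "\n")
  if (!anyNA(x$normalized_counts)) {
    cat("  normalized: ",
        paste(names(x$normalized_counts),
              sprintf("%.3f", x$normalized_counts),
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}
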