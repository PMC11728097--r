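#' Memantine threshold ladder
#'
#' Memantine, an uncompetitive voltage-dependent NMDA antagonist, is
#' modeled as raising the Mg2+ unblock threshold from CaMT to CaMem.
#' The four discrete operating points are -68 (untreated baseline), -65,
#' -63 and -55 mV.
#'
#' @param level integer 0-3.
#' @return CaMem in mV.
#' @export
memantine_threshold <- function(level) {
  ladder <- c(-68, -65, -63, -55)
  if (!is.numeric(level) || length(level) != 1L || !(level %in% 0:3)) {
    stop("memantine level must be an integer in 0..3")
  }
  ladder[level + 1L]
}

TRIAL_ARMS <- c("AD_untreated", "memantine", "DBS", "DBS_memantine")

#' Therapy specification
#'
#' @param arm one of `"AD_untreated"`, `"memantine"`, `"DBS"`,
#'   `"DBS_memantine"`.
#' @param memantine_level integer 0-3; the trial's memantine arms operate
#'   at level 3 (-55 mV), the nominal 10 uM point.
#' @param memantine_concentration nominal concentration, uM (metadata
#'   only; no concentration-response curve is modeled).
#' @param dbs_frequency DBS frequency, Hz (>= 40) for the DBS arms.
#' @return A `therapy_spec` list.
#' @export
therapy_spec <- function(arm = TRIAL_ARMS, memantine_level = 3L,
                         memantine_concentration = 10,
                         dbs_frequency = 40) {
  arm <- match.arg(arm)
  has_mem <- arm %in% c("memantine", "DBS_memantine")
  if (!has_mem) memantine_level <- 0L
  memantine_threshold(memantine_level)  # validates the level
  if (has_mem && memantine_level == 0L) {
    stop("a memantine arm needs memantine_level >= 1")
  }
  structure(list(arm = arm, memantine_level = as.integer(memantine_level),
                 memantine_concentration = memantine_concentration,
                 dbs_frequency = dbs_frequency,
                 has_memantine = has_mem,
                 has_dbs = arm %in% c("DBS", "DBS_memantine")),
            class = "therapy_spec")
}

#' Apply a therapy arm to a patient
#'
#' Memantine arms raise `ca_mem` on every NMDA-bearing (excitatory)
#' synapse network-wide (the drug is systemic); DBS arms superimpose the
#' 40 Hz train on the perforant-path lines via [add_dbs()]. The two
#' mechanisms touch disjoint state (synaptic thresholds vs. the stimulus
#' program), so the combined arm is order-independent. Pathology flags and
#' population sizes are never altered.
#'
#' @param network an AD-labeled `network_spec` (therapies are applied to
#'   patients, not to the control network).
#' @param program a `stimulus_program`.
#' @param spec a [therapy_spec()].
#' @return List `(network, program)` after therapy.
#' @export
apply_therapy <- function(network, program, spec) {
  stopifnot(inherits(network, "network_spec"),
            inherits(program, "stimulus_program"),
            inherits(spec, "therapy_spec"))
  if (network$label == "control") {
    stop("therapies are applied to AD networks, not the control network")
  }
  if (spec$has_memantine) {
    ca_mem <- memantine_threshold(spec$memantine_level)
    exc <- network$connections$kind == "excitatory"
    network$connections$ca_mem[exc] <- ca_mem
  }
  if (spec$has_dbs) {
    program <- add_dbs(program, spec$dbs_frequency)
  }
  list(network = network, program = program)
}
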