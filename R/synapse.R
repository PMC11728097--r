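#' Default synapse kinetic parameters
#'
#' Kinetic constants shared by every synapse in the network: the shift
#' registers advance one slot per time step (`dt`), each slot holding the
#' residual contribution (mV) of a presynaptic spike of a given age. AMPA
#' contributions decay fast, NMDA slowly, GABA at an intermediate rate.
#'
#' @param dt time step, ms.
#' @param register_length number of slots per register; contributions older
#'   than `register_length * dt` expire.
#' @param tau_ampa,tau_nmda,tau_gaba decay time constants, ms.
#' @param ltp_duration duration of long-term potentiation once triggered,
#'   in time steps.
#' @param ltp_gain multiplicative weight gain while potentiated (>= 1).
#' @return A named list of kinetic constants.
#' @export
synapse_params <- function(dt = 1, register_length = 80,
                           tau_ampa = 5, tau_nmda = 50, tau_gaba = 10,
                           ltp_duration = 200, ltp_gain = 1.5) {
  stopifnot(dt > 0, register_length >= 1, tau_ampa > 0, tau_nmda > 0,
            tau_gaba > 0, ltp_duration >= 0, ltp_gain >= 1)
  list(dt = dt, register_length = as.integer(register_length),
       tau_ampa = tau_ampa, tau_nmda = tau_nmda, tau_gaba = tau_gaba,
       ltp_duration = as.integer(ltp_duration), ltp_gain = ltp_gain)
}

#' Gating parameters for the NMDA Mg2+ block
#'
#' `ca_mt` is the membrane potential at which the Mg2+ block of the NMDA
#' channel is removed (-68 mV in the untreated model). Memantine, a
#' voltage-dependent NMDA antagonist, is modeled as raising this threshold
#' to `ca_mem` (>= `ca_mt`); without memantine `ca_mem == ca_mt`.
#'
#' @param ca_mt Mg2+ unblock threshold, mV.
#' @param ca_mem therapy-modified threshold, mV; defaults to `ca_mt`.
#' @param rest_potential resting potential, mV.
#' @return A named list with `ca_mt`, `ca_mem` and `rest_potential`.
#' @export
gating_params <- function(ca_mt = -68, ca_mem = ca_mt, rest_potential = -80) {
  if (ca_mem < ca_mt) {
    stop("ca_mem must be >= ca_mt: memantine only raises the unblock threshold")
  }
  list(ca_mt = ca_mt, ca_mem = ca_mem, rest_potential = rest_potential)
}

#' Enumerated excitotoxicity intensities
#'
#' The excitotoxic drive scale `power_b` takes one of four discrete values;
#' 9 equals the normal drive scale `power_a` (no excitotoxicity), the
#' higher levels model increasing extracellular glutamate.
#' @export
EXCITOTOXICITY_LEVELS <- c(9, 56.7, 63, 135)

#' Construct a synapse state
#'
#' A synapse carries two fixed-length shift registers: `e_register` for the
#' AMPA (or GABA, when inhibitory) contribution and `m_register` for the
#' NMDA contribution. Each slot holds the residual postsynaptic
#' contribution (mV) of the spike that arrived that many steps ago. The
#' summarized potential S is rebuilt from the registers every step; when S
#' exceeds the effective unblock threshold the NMDA component becomes
#' permeable and LTP is triggered.
#'
#' @param kind `"excitatory"` (AMPA + NMDA) or `"inhibitory"` (GABA only).
#' @param base_weight entry contribution per spike, mV; must be > 0 for
#'   excitatory and < 0 for inhibitory synapses.
#' @param nmda_weight NMDA entry contribution per spike, mV (ignored and
#'   forced to 0 for inhibitory synapses).
#' @param power_a drive scale under normal transmission (dimensionless).
#' @param clog auxiliary regulation scalar, multiplicative on the
#'   inhibitory contribution (default 1, i.e. inert).
#' @param gating a [gating_params()] list.
#' @param params a [synapse_params()] list.
#' @return A `synapse_state` object (S3 list).
#' @export
synapse_state <- function(kind = c("excitatory", "inhibitory"),
                          base_weight = 1, nmda_weight = 0.5,
                          power_a = 9, clog = 1,
                          gating = gating_params(),
                          params = synapse_params()) {
  kind <- match.arg(kind)
  if (kind == "excitatory" && base_weight <= 0) {
    stop("excitatory synapses need base_weight > 0")
  }
  if (kind == "inhibitory") {
    if (base_weight >= 0) stop("inhibitory synapses need base_weight < 0")
    nmda_weight <- 0
  }
  L <- params$register_length
  structure(list(
    kind = kind,
    base_weight = base_weight,
    nmda_weight = nmda_weight,
    e_register = numeric(L),
    m_register = numeric(L),
    regulation = list(power_a = power_a, power_b = power_a, clog = clog,
                      excitotoxic = FALSE, excitotoxicity_level = 9),
    gating = gating,
    ltp_timer = 0L,
    ltp_gain_active = 1,
    nmda_open = FALSE,
    s = gating$rest_potential,
    params = params
  ), class = "synapse_state")
}

decay_factor <- function(state) {
  tau <- if (state$kind == "excitatory") state$params$tau_ampa else
    state$params$tau_gaba
  exp(-state$params$dt / tau)
}

#' Excitatory synapse input: advance the shift registers
#'
#' Shifts both registers one slot toward expiry (applying one step of
#' kernel decay) and, if a presynaptic spike arrived this step, loads the
#' entry slot with `base_weight * ltp_gain` (AMPA) and
#' `nmda_weight * ltp_gain` (NMDA).
#'
#' @param state a `synapse_state`, must be excitatory.
#' @param spike_arrived logical scalar.
#' @return The updated `synapse_state`.
#' @export
in_ex <- function(state, spike_arrived) {
  stopifnot(inherits(state, "synapse_state"), is.logical(spike_arrived),
            length(spike_arrived) == 1L)
  if (state$kind != "excitatory") {
    stop("in_ex() is defined for excitatory synapses only")
  }
  shift_registers(state, spike_arrived)
}

shift_registers <- function(state, spike_arrived) {
  L <- state$params$register_length
  de <- decay_factor(state)
  dm <- exp(-state$params$dt / state$params$tau_nmda)
  g <- state$ltp_gain_active
  e_new <- if (spike_arrived) state$base_weight * g else 0
  m_new <- if (spike_arrived) state$nmda_weight * g else 0
  state$e_register <- c(e_new, state$e_register[-L] * de)
  state$m_register <- c(m_new, state$m_register[-L] * dm)
  state
}

#' Voltage-dependent NMDA gate
#'
#' The Mg2+ block is removed when the summarized potential exceeds the
#' effective threshold `ca_mem` (equal to `ca_mt` without memantine). While
#' open, the NMDA register contributes to the postsynaptic drive and LTP is
#' (re)triggered.
#'
#' @param s summarized potential, mV.
#' @param gating a [gating_params()] list.
#' @return `"open"` or `"blocked"`.
#' @export
nmda_gate <- function(s, gating) {
  if (!is.finite(s)) stop("non-finite summarized potential")
  if (s > gating$ca_mem) "open" else "blocked"
}

#' Summarized potential of a synapse
#'
#' S = rest_potential + power * sum(e_register), plus the NMDA component
#' sum(m_register) when the gate is open. `power` is `power_a` under normal
#' transmission and `power_b` in neurodegenerative (excitotoxic) mode. For
#' inhibitory synapses the register sum is negative and scaled by `clog`,
#' and the NMDA machinery is inert.
#'
#' @param state a `synapse_state`.
#' @return S in mV (scalar). Use [synapse_step()] to also update the cached
#'   value and LTP bookkeeping.
#' @export
summarize_potential <- function(state) {
  if (!all(is.finite(state$e_register)) || !all(is.finite(state$m_register))) {
    stop("non-finite register content")
  }
  reg <- state$regulation
  power <- if (reg$excitotoxic) reg$power_b else reg$power_a
  rp <- state$gating$rest_potential
  if (state$kind == "inhibitory") {
    return(rp + power * reg$clog * sum(state$e_register))
  }
  s_ampa <- rp + power * sum(state$e_register)
  if (nmda_gate(s_ampa, state$gating) == "open") {
    s_ampa + sum(state$m_register)
  } else {
    s_ampa
  }
}

#' Advance a synapse one time step
#'
#' Convenience driver used by the pure-R reference path and the unit
#' tests: shifts the registers, recomputes S, applies the NMDA gate and
#' performs the LTP bookkeeping (trigger on open, countdown otherwise).
#'
#' @param state a `synapse_state`.
#' @param spike_arrived logical: did a presynaptic spike arrive this step?
#' @return The updated state with `s` cached.
#' @export
synapse_step <- function(state, spike_arrived) {
  state <- shift_registers(state, spike_arrived)
  reg <- state$regulation
  power <- if (reg$excitotoxic) reg$power_b else reg$power_a
  rp <- state$gating$rest_potential
  if (state$kind == "inhibitory") {
    state$s <- rp + power * reg$clog * sum(state$e_register)
    state$nmda_open <- FALSE
    return(state)
  }
  s_ampa <- rp + power * sum(state$e_register)
  state$nmda_open <- state$nmda_weight != 0 &&
    nmda_gate(s_ampa, state$gating) == "open"
  if (state$nmda_open) {
    state$s <- s_ampa + sum(state$m_register)
    state$ltp_timer <- state$params$ltp_duration
    state$ltp_gain_active <- state$params$ltp_gain
  } else {
    state$s <- s_ampa
    if (state$ltp_timer > 0L) {
      state$ltp_timer <- state$ltp_timer - 1L
      if (state$ltp_timer == 0L) state$ltp_gain_active <- 1
    }
  }
  state
}

#' Switch a synapse into neurodegenerative (excitotoxic) mode
#'
#' Sets the excitotoxic drive scale `power_b` to one of the enumerated
#' intensities and marks the synapse as excitotoxic, so that
#' [summarize_potential()] uses `power_b` in place of `power_a`. Level 9
#' equals the normal drive scale, so behavior at level 9 matches control.
#'
#' @param state a `synapse_state`.
#' @param level one of 9, 56.7, 63, 135.
#' @return The updated state.
#' @export
apply_excitotoxicity <- function(state, level) {
  if (!is.numeric(level) || length(level) != 1L ||
      !any(abs(level - EXCITOTOXICITY_LEVELS) < 1e-9)) {
    stop("excitotoxicity level must be one of ",
         paste(EXCITOTOXICITY_LEVELS, collapse = ", "))
  }
  state$regulation$power_b <- level
  state$regulation$excitotoxic <- TRUE
  state$regulation$excitotoxicity_level <- level
  state
}

#' Run a synapse over a spike train
#'
#' Feeds a 0/1 spike sequence through [synapse_step()] and returns the S
#' time-course, one value per step.
#'
#' @param state a `synapse_state`.
#' @param spikes logical or 0/1 vector of presynaptic arrivals.
#' @return Numeric vector of summarized potentials, same length as
#'   `spikes`, with attribute `"nmda_open"`: logical vector marking the
#'   steps on which the Mg2+ block was removed.
#' @export
synapse_run <- function(state, spikes) {
  out <- numeric(length(spikes))
  open <- logical(length(spikes))
  for (i in seq_along(spikes)) {
    state <- synapse_step(state, as.logical(spikes[i]))
    out[i] <- state$s
    open[i] <- isTRUE(state$nmda_open)
  }
  structure(out, nmda_open = open)
}
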