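#' External input programs: theta-nested gamma bursts, septal drive, DBS
#'
#' The hippocampal network is driven by three families of external lines:
#' nine perforant-path lines from entorhinal cortex layer II (Ex1-Ex9, of
#' which Ex8 and Ex9 are silent), direct EC layer III lines to CA1 in
#' antiphase with EC2, and nine septal GABAergic lines (T1-T9) that
#' rhythmically disinhibit the hippocampal interneurons at theta frequency.
#' Active EC lines carry bursts of `burst_size` action potentials at
#' `intra_burst_frequency`, repeated at `theta_frequency` and phase-shifted
#' between lines. An optional DBS train superimposes a regular
#' `dbs$frequency` spike train on every perforant-path line.
#'
#' @name stimulus
NULL

EC2_LINES <- paste0("Ex", 1:9)
EC2_ACTIVE <- paste0("Ex", 1:7)
EC2_SILENT <- paste0("Ex", 8:9)
EC3_LINES <- paste0("EC3_", 1:8)
SEPTAL_LINES <- paste0("T", 1:9)

# Burst spike times for one line, wrapped circularly into [0, duration).
# Wrapping (rather than truncating) keeps the per-line spike count exact on
# whole-cycle durations regardless of the line's phase offset.
burst_line_times <- function(duration, dt, theta_hz, burst_size, burst_hz,
                             phase) {
  cycle <- 1000 / theta_hz
  n_cycles <- floor(duration * theta_hz / 1000)
  if (n_cycles < 1) return(numeric(0))
  isi <- 1000 / burst_hz
  starts <- (seq_len(n_cycles) - 1) * cycle
  t <- as.vector(outer((seq_len(burst_size) - 1) * isi, starts, `+`)) + phase
  t <- round(t / dt) * dt
  t <- t %% (n_cycles * cycle)
  sort(unique(round(t, 9)))
}

#' Build the standard EC2/EC3/septal stimulus program
#'
#' @param duration total duration, ms; should be a whole number of theta
#'   cycles for clean spike counting.
#' @param theta_frequency inter-burst (theta) frequency, Hz; must lie in
#'   `[4, 12]`.
#' @param burst_size action potentials per burst.
#' @param intra_burst_frequency within-burst frequency, Hz.
#' @param dt time step, ms.
#' @param phase_offsets named or unnamed numeric vector of per-line phase
#'   offsets (ms) for Ex1-Ex7; default spreads the seven active lines
#'   evenly over one theta cycle.
#' @param septal logical: include the septal theta lines?
#' @return A `stimulus_program` object: list with `duration`, `dt`,
#'   stimulus parameters, `dbs` (NULL until [add_dbs()]), and `events`, a
#'   data.frame of (`line_id`, `t_ms`) sorted by line then time.
#' @export
make_ec_program <- function(duration = 2000, theta_frequency = 8,
                            burst_size = 5, intra_burst_frequency = 100,
                            dt = 1, phase_offsets = NULL, septal = TRUE) {
  if (duration <= 0) stop("duration must be positive")
  if (theta_frequency < 4 || theta_frequency > 12) {
    stop("stimulus.theta_hz: theta frequency must lie in [4, 12] Hz")
  }
  cycle <- 1000 / theta_frequency
  if (is.null(phase_offsets)) {
    phase_offsets <- (seq_along(EC2_ACTIVE) - 1) * cycle / length(EC2_ACTIVE)
  }
  stopifnot(length(phase_offsets) == length(EC2_ACTIVE))

  ev <- list()
  for (i in seq_along(EC2_ACTIVE)) {
    t <- burst_line_times(duration, dt, theta_frequency, burst_size,
                          intra_burst_frequency, phase_offsets[i])
    if (length(t)) ev[[EC2_ACTIVE[i]]] <- t
  }
  # EC3 mirrors the EC2 burst structure half a theta cycle later, so strong
  # EC2 input coincides with weak EC3 input and vice versa.
  ec3_phase <- rep(phase_offsets, length.out = length(EC3_LINES)) + cycle / 2
  for (i in seq_along(EC3_LINES)) {
    t <- burst_line_times(duration, dt, theta_frequency, burst_size,
                          intra_burst_frequency, ec3_phase[i])
    if (length(t)) ev[[EC3_LINES[i]]] <- t
  }
  if (septal) {
    # Septal GABAergic cells fire in the first half of each theta cycle,
    # silencing hippocampal interneurons while the EC2 bursts arrive
    # (rhythmic disinhibition); modeled as 50% duty-cycle 100 Hz trains.
    n_cycles <- floor(duration * theta_frequency / 1000)
    half <- seq(0, cycle / 2 - 1, by = 10)
    for (i in seq_along(SEPTAL_LINES)) {
      t <- as.vector(outer(half, (seq_len(n_cycles) - 1) * cycle, `+`))
      t <- sort(unique(round(t / dt) * dt)) %% (n_cycles * cycle)
      ev[[SEPTAL_LINES[i]]] <- sort(unique(t))
    }
  }
  events <- data.frame(
    line_id = rep(names(ev), lengths(ev)),
    t_ms = unlist(ev, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$line_id, events$t_ms), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(duration = duration, dt = dt,
                 theta_frequency = theta_frequency,
                 burst_size = burst_size,
                 intra_burst_frequency = intra_burst_frequency,
                 phase_offsets = phase_offsets,
                 dbs = NULL, events = events),
            class = "stimulus_program")
}

#' Superimpose a DBS train on the perforant-path lines
#'
#' Deep brain stimulation is modeled as oscillations in the perforant
#' pathway: a regular spike train at `frequency` (>= 40 Hz) merged onto
#' every EC2 line, including the normally silent Ex8 and Ex9. Spike times
#' that collide within one time step collapse to a single event, so the
#' operation is idempotent.
#'
#' @param program a `stimulus_program`.
#' @param frequency DBS frequency, Hz (default 40).
#' @return The augmented `stimulus_program` with `dbs` metadata set.
#' @export
add_dbs <- function(program, frequency = 40) {
  stopifnot(inherits(program, "stimulus_program"))
  if (frequency < 40) stop("DBS frequency must be at least 40 Hz")
  period <- 1000 / frequency
  train <- round(seq(0, program$duration - period, by = period) /
                   program$dt) * program$dt
  ev <- program$events
  keep <- ev[!(ev$line_id %in% EC2_LINES), , drop = FALSE]
  ec2 <- ev[ev$line_id %in% EC2_LINES, , drop = FALSE]
  merged <- lapply(EC2_LINES, function(l) {
    t <- sort(unique(c(ec2$t_ms[ec2$line_id == l], train)))
    data.frame(line_id = rep(l, length(t)), t_ms = t,
               stringsAsFactors = FALSE)
  })
  events <- rbind(keep, do.call(rbind, merged))
  events <- events[order(events$line_id, events$t_ms), , drop = FALSE]
  rownames(events) <- NULL
  program$events <- events
  program$dbs <- list(frequency = frequency, target = EC2_LINES)
  program
}

#' Spike count per line of a stimulus program
#'
#' @param program a `stimulus_program`.
#' @return Named integer vector of per-line event counts (lines with no
#'   events are absent).
#' @export
line_counts <- function(program) {
  tab <- table(program$events$line_id)
  stats::setNames(as.integer(tab), names(tab))
}
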