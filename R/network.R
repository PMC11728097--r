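#' Neuron parameters
#'
#' Every cell is a 16-compartment leaky integrate-and-fire neuron:
#' compartment 1 is the soma (the only strongly leaky compartment),
#' compartment 2 the axon initial segment, compartments 3-9 one dendritic
#' branch and 10-16 the second, each a proximal-to-distal chain coupled to
#' the soma. Perforant-path and EC3 inputs arrive on distal compartments
#' (13-16), mossy-fiber and Schaffer inputs on proximal ones (3-6), somatic
#' inhibition on compartment 1.
#'
#' @param tau_m somatic membrane time constant, ms.
#' @param tau_dend dendritic leak time constant, ms (weak).
#' @param spike_threshold somatic spike threshold, mV.
#' @param rest_potential resting potential, mV.
#' @param axial axial coupling coefficient between neighboring
#'   compartments, 1/ms.
#' @param refractory absolute refractory period, ms.
#' @param n_compartments number of compartments (16 in the network model).
#' @return Named list of neuron constants.
#' @export
neuron_params <- function(tau_m = 20, tau_dend = 100, spike_threshold = -54,
                          rest_potential = -80, axial = 2, refractory = 5,
                          n_compartments = 16) {
  stopifnot(spike_threshold > rest_potential, tau_m > 0, axial >= 0,
            refractory >= 0, n_compartments >= 1)
  list(tau_m = tau_m, tau_dend = tau_dend,
       spike_threshold = spike_threshold,
       rest_potential = rest_potential, axial = axial,
       refractory = refractory, n_compartments = as.integer(n_compartments))
}

#' Compartment adjacency of the 16-compartment cell
#'
#' @param n_compartments number of compartments; 16 gives the standard
#'   soma/axon/two-branch layout, smaller values a soma-rooted chain.
#' @return List of integer vectors, `[[c]]` = neighbors of compartment c.
#' @export
compartment_graph <- function(n_compartments = 16) {
  n <- as.integer(n_compartments)
  if (n == 1L) return(list(integer(0)))
  nb <- vector("list", n)
  if (n < 16L) {
    for (c in seq_len(n)) {
      nb[[c]] <- c(if (c > 1L) c - 1L, if (c < n) c + 1L)
    }
    return(nb)
  }
  edge <- function(a, b) {
    nb[[a]] <<- c(nb[[a]], b)
    nb[[b]] <<- c(nb[[b]], a)
  }
  edge(1L, 2L)                      # soma - axon
  edge(1L, 3L)                      # soma - branch A root
  for (c in 3L:8L) edge(c, c + 1L)  # branch A chain 3..9
  edge(1L, 10L)                     # soma - branch B root
  for (c in 10L:15L) edge(c, c + 1L)  # branch B chain 10..16
  nb
}

#' Advance a neuron one time step (pure-R reference)
#'
#' Forward-Euler leaky integration with nearest-neighbor axial coupling,
#' sub-stepped for stability. The soma (compartment 1) carries the strong
#' leak and the spike mechanism: crossing `spike_threshold` from below
#' emits a spike and resets soma and axon to rest for `refractory` ms.
#'
#' @param state list with `v` (numeric, one mV value per compartment) and
#'   `refractory` (ms remaining).
#' @param drive per-compartment input current, mV/ms.
#' @param dt time step, ms.
#' @param params a [neuron_params()] list.
#' @param substeps Euler substeps per dt.
#' @return List `(state, spiked)`.
#' @export
advance_neuron <- function(state, drive, dt, params = neuron_params(),
                           substeps = 5L) {
  if (!all(is.finite(drive))) stop("non-finite synaptic drive")
  stopifnot(dt > 0, length(drive) == length(state$v))
  n <- length(state$v)
  nb <- compartment_graph(n)
  v <- state$v
  rp <- params$rest_potential
  h <- dt / substeps
  for (s in seq_len(substeps)) {
    ax <- vapply(seq_len(n), function(c) {
      if (length(nb[[c]])) sum(v[nb[[c]]] - v[c]) else 0
    }, numeric(1))
    leak <- c((rp - v[1]) / params$tau_m,
              if (n > 1L) (rp - v[-1]) / params$tau_dend)
    v <- v + h * (leak + params$axial * ax + drive)
  }
  spiked <- FALSE
  if (state$refractory > 0) {
    state$refractory <- max(0, state$refractory - dt)
    v[1] <- rp
    if (n > 1L) v[2] <- rp
  } else if (v[1] >= params$spike_threshold) {
    spiked <- TRUE
    v[1] <- rp
    if (n > 1L) v[2] <- rp
    state$refractory <- params$refractory
  }
  state$v <- v
  list(state = state, spiked = spiked)
}

#' Rest state for a neuron
#' @param params a [neuron_params()] list.
#' @return List with `v` at rest and zero refractory time.
#' @export
neuron_rest_state <- function(params = neuron_params()) {
  list(v = rep(params$rest_potential, params$n_compartments), refractory = 0)
}

#' Default synaptic weight table
#'
#' Base weights (`w_e`: AMPA/GABA entry contribution, mV per spike; `w_m`:
#' NMDA entry contribution) per connection class. These are the free
#' calibration constants of the model: the EC2 classes set how hard the
#' perforant path drives principal cells and interneurons (and therefore
#' how much excitotoxicity and memantine can modulate them), the
#' within-hippocampus classes set the feedforward DG->CA3->CA1 relay and
#' the strength of feedback inhibition.
#'
#' @return Named list; each element is `c(w_e, w_m)`.
#' @export
default_weights <- function() {
  list(
    ec2_granule      = c(1.20, 0.10),
    ec2_ca3_pyr      = c(0.15, 0.00),
    ec2_dg_basket    = c(0.13, 1.00),
    ec2_ca3_basket   = c(0.20, 1.20),
    ec2_ca3_basket_strong = c(0.40, 1.20),
    ec3_ca1          = c(0.70, 0.20),
    mossy_g_mc       = c(0.50, 0.00),
    mc_granule       = c(0.40, 0.00),
    mossy_fiber      = c(1.20, 0.00),
    schaffer         = c(0.70, 0.00),
    g_basket         = c(0.70, 0.00),
    ca3p_olm         = c(0.50, 0.00),
    ca3p_basket      = c(0.50, 0.00),
    basket_dg        = c(-2.60, 0.00),
    basket_ca3       = c(-0.15, 0.00),
    basket_ca1       = c(-1.00, 0.00),
    olm_principal    = c(-0.60, 0.00),
    septal_intn      = c(-0.50, 0.00)
  )
}

POPULATION_SIZES <- c(DG_granule = 8, DG_basket = 2, DG_mossy = 1,
                      CA3_pyramidal = 16, CA3_basket = 2, CA3_OLM = 1,
                      CA1_pyramidal = 8, CA1_basket = 2, CA1_OLM = 1)

cell_table <- function() {
  mk <- function(ids, population, region, principal, tau_m, refractory) {
    data.frame(cell_id = ids, population = population, region = region,
               principal = principal, tau_m = tau_m,
               refractory = refractory, stringsAsFactors = FALSE)
  }
  rbind(
    mk(paste0("G", 1:8), "DG_granule", "DG", TRUE, 20, 5),
    mk(c("B1", "B2"), "DG_basket", "DG", FALSE, 10, 4),
    mk("MC1", "DG_mossy", "DG", FALSE, 20, 5),
    mk(paste0("CA3_P", 1:16), "CA3_pyramidal", "CA3", TRUE, 20, 5),
    mk(c("B3", "B4"), "CA3_basket", "CA3", FALSE, 10, 4),
    mk("OLM1", "CA3_OLM", "CA3", FALSE, 10, 2),
    mk(paste0("CA1_P", 1:8), "CA1_pyramidal", "CA1", TRUE, 20, 5),
    mk(c("B5", "B6"), "CA1_basket", "CA1", FALSE, 10, 4),
    mk("OLM2", "CA1_OLM", "CA1", FALSE, 10, 2)
  )
}

#' Build the control (pathology-free) hippocampal network
#'
#' Constructs the full DG-CA3-CA1 microcircuit: 8 DG granule cells
#' (G1-G8), 2 DG basket cells, 1 mossy cell, 16 CA3 pyramidal cells
#' (P1-P16), 8 CA1 pyramidal cells (P1-P8), basket cells B1-B6 (two per
#' region), one O-LM cell per CA3 and CA1, with EC2 perforant-path input
#' to DG/CA3 and their interneurons, EC3 input to CA1, mossy fibers
#' DG->CA3, Schaffer collaterals CA3->CA1, feedback inhibition from basket
#' and O-LM cells, and theta-rhythmic septal disinhibition of the
#' interneurons. The nine septal GABAergic cells (T1-T9) are represented
#' as external drive lines. Deterministic: no RNG is consumed.
#'
#' @param weights a [default_weights()]-shaped list of per-class weights.
#' @param neuron a [neuron_params()] list (interneuron `tau_m` and
#'   `refractory` are taken from the cell table).
#' @param gating a [gating_params()] list applied to every synapse.
#' @param power_a normal drive scale.
#' @param clog auxiliary inhibitory regulation scalar.
#' @return A `network_spec` object: list with `cells`, `connections`,
#'   `populations`, `neuron`, `label`, `severity`,
#'   `excitotoxicity_level`.
#' @export
build_control_network <- function(weights = default_weights(),
                                  neuron = neuron_params(),
                                  gating = gating_params(),
                                  power_a = 9, clog = 1) {
  stopifnot(setequal(names(weights), names(default_weights())))
  cells <- cell_table()
  rows <- list()
  add <- function(source, source_kind, target, comp, class, wclass,
                  kind = "excitatory") {
    w <- weights[[wclass]]
    rows[[length(rows) + 1L]] <<- data.frame(
      source = source, source_kind = source_kind, target = target,
      target_comp = as.integer(comp), kind = kind,
      w_e = w[1], w_m = if (kind == "excitatory") w[2] else 0,
      class = class, enabled = TRUE, stringsAsFactors = FALSE)
  }

  ## --- perforant path (EC2) -------------------------------------------
  for (i in 1:8) {                      # two EC2 lines per granule cell
    add(paste0("Ex", i), "external", paste0("G", i), 14,
        "EC2_granule", "ec2_granule")
    add(paste0("Ex", i %% 9 + 1), "external", paste0("G", i), 15,
        "EC2_granule", "ec2_granule")
  }
  for (i in 1:9) {                      # each line contacts two CA3 cells
    add(paste0("Ex", i), "external", paste0("CA3_P", 2 * ((i - 1) %% 8) + 1),
        14, "EC2_CA3_pyr", "ec2_ca3_pyr")
    add(paste0("Ex", i), "external", paste0("CA3_P", 2 * ((i - 1) %% 8) + 2),
        14, "EC2_CA3_pyr", "ec2_ca3_pyr")
  }
  ## EC2 onto interneuron distal dendrites (DG and CA3 basket cells)
  ec2_basket <- list(B1 = c(1, 2, 3, 4, 9), B2 = c(5, 6, 7, 8, 9),
                     B3 = 1:9, B4 = 1:9)
  for (b in names(ec2_basket)) {
    for (i in ec2_basket[[b]]) {
      # CA3 basket perforant synapses are heterogeneous: odd lines carry
      # the stronger variant (graded, not all-or-none, memantine block)
      wclass <- if (b %in% c("B1", "B2")) "ec2_dg_basket"
        else if (i %% 2 == 1) "ec2_ca3_basket_strong" else "ec2_ca3_basket"
      add(paste0("Ex", i), "external", b, 14, "EC2_interneuron", wclass)
    }
  }

  ## --- EC3 -> CA1 ------------------------------------------------------
  for (i in 1:8) {
    add(paste0("EC3_", i), "external", paste0("CA1_P", i), 14,
        "other", "ec3_ca1")
  }

  ## --- dentate gyrus internal -----------------------------------------
  for (i in 1:8) add(paste0("G", i), "cell", "MC1", 4, "other", "mossy_g_mc")
  for (i in 1:8) add("MC1", "cell", paste0("G", i), 4, "other", "mc_granule")
  for (i in 1:8) {                      # granule feedback onto DG baskets
    add(paste0("G", i), "cell", if (i <= 4) "B1" else "B2", 4,
        "other", "g_basket")
  }

  ## --- mossy fibers DG -> CA3 -----------------------------------------
  for (i in 1:8) {
    add(paste0("G", i), "cell", paste0("CA3_P", 2 * i - 1), 4,
        "other", "mossy_fiber")
    add(paste0("G", i), "cell", paste0("CA3_P", 2 * i), 4,
        "other", "mossy_fiber")
  }

  ## --- Schaffer collaterals CA3 -> CA1 (2:1 convergence) --------------
  for (j in 1:8) {
    add(paste0("CA3_P", 2 * j - 1), "cell", paste0("CA1_P", j), 4,
        "other", "schaffer")
    add(paste0("CA3_P", 2 * j), "cell", paste0("CA1_P", j), 4,
        "other", "schaffer")
  }

  ## --- O-LM and CA1 basket drive --------------------------------------
  for (p in c(1, 5, 9, 13)) add(paste0("CA3_P", p), "cell", "OLM1", 4,
                                "other", "ca3p_olm")
  for (p in c(2, 6, 10, 14)) add(paste0("CA3_P", p), "cell", "OLM2", 4,
                                 "other", "ca3p_olm")
  for (p in c(1, 3, 5, 7)) add(paste0("CA3_P", p), "cell", "B5", 4,
                               "other", "ca3p_basket")
  for (p in c(9, 11, 13, 15)) add(paste0("CA3_P", p), "cell", "B6", 4,
                                  "other", "ca3p_basket")

  ## --- inhibition ------------------------------------------------------
  for (i in 1:8) {
    add("B1", "cell", paste0("G", i), 1, "other", "basket_dg",
        "inhibitory")
    add("B2", "cell", paste0("G", i), 1, "other", "basket_dg",
        "inhibitory")
  }
  for (p in 1:16) {
    add(if (p %% 2 == 1) "B3" else "B4", "cell", paste0("CA3_P", p), 1,
        "other", "basket_ca3", "inhibitory")
    add("OLM1", "cell", paste0("CA3_P", p), 14, "other", "olm_principal",
        "inhibitory")
  }
  for (p in 1:16) {  # every CA3 pyramidal cell gets both basket cells
    add(if (p %% 2 == 1) "B4" else "B3", "cell", paste0("CA3_P", p), 1,
        "other", "basket_ca3", "inhibitory")
  }
  for (j in 1:8) {
    add(if (j <= 4) "B5" else "B6", "cell", paste0("CA1_P", j), 1,
        "other", "basket_ca1", "inhibitory")
    add("OLM2", "cell", paste0("CA1_P", j), 14, "other", "olm_principal",
        "inhibitory")
  }

  ## --- septal disinhibition (T1-T9 as external lines) ------------------
  septal_targets <- c(T1 = "B1", T2 = "B2", T3 = "B3", T4 = "B4",
                      T5 = "B5", T6 = "B6", T7 = "OLM1", T8 = "OLM2",
                      T9 = "MC1")
  for (t in names(septal_targets)) {
    add(t, "external", septal_targets[[t]], 1, "other", "septal_intn",
        "inhibitory")
  }

  connections <- do.call(rbind, rows)
  connections$conn_id <- seq_len(nrow(connections))
  connections$excitotoxic <- FALSE
  connections$power_a <- power_a
  connections$power_b <- power_a
  connections$ca_mt <- gating$ca_mt
  connections$ca_mem <- gating$ca_mem
  connections$clog <- clog
  rownames(connections) <- NULL

  bad <- connections$kind == "inhibitory" &
    !(connections$source %in%
        c("B1", "B2", "B3", "B4", "B5", "B6", "OLM1", "OLM2",
          SEPTAL_LINES))
  stopifnot(!any(bad))

  structure(list(
    populations = data.frame(name = names(POPULATION_SIZES),
                             size = as.integer(POPULATION_SIZES),
                             stringsAsFactors = FALSE),
    cells = cells,
    connections = connections,
    neuron = neuron,
    label = "control",
    severity = 0,
    excitotoxicity_level = 9
  ), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$label,
      if (x$label != "control") sprintf("(severity %.2f, excitotoxicity %g)",
                                        x$severity, x$excitotoxicity_level),
      "\n")
  cat("  cells:", nrow(x$cells), " connections:", nrow(x$connections),
      sprintf("(%d disabled)\n", sum(!x$connections$enabled)))
  invisible(x)
}
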