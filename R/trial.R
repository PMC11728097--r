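#' Trial design
#'
#' The randomized in silico trial: a 100-network AD cohort, 20 randomly
#' sampled patients, four arms (untreated AD, memantine, DBS,
#' DBS+memantine). In the default within-subject mode every patient is
#' simulated under all four arms (80 endpoint simulations); between-subject
#' mode randomizes each patient to one arm at a stated ratio. Every
#' randomized stage draws its own child seed deterministically from
#' `master_seed`.
#'
#' @param master_seed integer master seed.
#' @param n_patients patients sampled from the cohort.
#' @param mode `"within"` (all arms per patient) or `"between"`.
#' @param ratio arm randomization ratio for between-subject mode
#'   (length 4).
#' @param memantine_level operating point of the memantine arms (0-3).
#' @param dbs_frequency DBS frequency, Hz.
#' @param cohort a [cohort_spec()]; its `seed` is replaced by a child of
#'   `master_seed`.
#' @param weights a [default_weights()]-shaped weight table.
#' @param engine an [engine_params()] list.
#' @param theta_frequency,burst_size,intra_burst_frequency stimulus
#'   parameters for [make_ec_program()].
#' @return A `trial_design` list.
#' @export
trial_design <- function(master_seed = 1L, n_patients = 20L,
                         mode = c("within", "between"),
                         ratio = c(1, 1, 1, 1),
                         memantine_level = 3L, dbs_frequency = 40,
                         cohort = cohort_spec(),
                         weights = default_weights(),
                         engine = engine_params(),
                         theta_frequency = 8, burst_size = 5,
                         intra_burst_frequency = 100) {
  mode <- match.arg(mode)
  if (length(ratio) != length(TRIAL_ARMS)) {
    stop("ratio must have one entry per arm (", length(TRIAL_ARMS), ")")
  }
  structure(list(master_seed = as.integer(master_seed),
                 n_patients = as.integer(n_patients), mode = mode,
                 ratio = ratio, memantine_level = as.integer(memantine_level),
                 dbs_frequency = dbs_frequency, cohort = cohort,
                 weights = weights, engine = engine,
                 theta_frequency = theta_frequency, burst_size = burst_size,
                 intra_burst_frequency = intra_burst_frequency),
            class = "trial_design")
}

# One master seed expands into per-stage child seeds so each stage is
# independently reproducible.
derive_seeds <- function(master_seed, n_patients) {
  old <- .Random.seed_exists()
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max, 4 + n_patients)
  .restore_seed(old)
  list(cohort = s[1], sampling = s[2], assignment = s[3], control = s[4],
       patients = s[4 + seq_len(n_patients)])
}

#' Assign patients to trial arms
#'
#' Within-subject mode maps every patient to all four arms; between-subject
#' mode uses simple randomization at `ratio` (honored in expectation).
#' Deterministic given `seed`.
#'
#' @param patients a `cohort` of sampled patients.
#' @param mode `"within"` or `"between"`.
#' @param ratio length-4 numeric randomization ratio (between mode).
#' @param seed integer seed.
#' @return data.frame with `network_id` and `arm`.
#' @export
assign_arms <- function(patients, mode = c("within", "between"),
                        ratio = c(1, 1, 1, 1), seed = 1L) {
  mode <- match.arg(mode)
  if (length(patients) == 0) stop("no patients to assign")
  if (length(ratio) != length(TRIAL_ARMS)) {
    stop("ratio must have one entry per arm (", length(TRIAL_ARMS), ")")
  }
  ids <- vapply(patients, `[[`, character(1), "network_id")
  if (mode == "within") {
    data.frame(network_id = rep(ids, each = length(TRIAL_ARMS)),
               arm = rep(TRIAL_ARMS, length(ids)),
               stringsAsFactors = FALSE)
  } else {
    old <- .Random.seed_exists()
    set.seed(seed)
    arm <- sample(TRIAL_ARMS, length(ids), replace = TRUE,
                  prob = ratio / sum(ratio))
    .restore_seed(old)
    data.frame(network_id = ids, arm = arm, stringsAsFactors = FALSE)
  }
}

#' Run the full randomized in silico trial
#'
#' Pipeline: generate the 100-network cohort, sample `n_patients`
#' patients, assign arms, apply each arm's therapy operators, simulate,
#' normalize each region's principal-cell spike count against the single
#' control reference run (control network, non-DBS program), and analyze
#' the endpoint table with ANOVA + Tukey HSD. Fully reproducible from
#' `design$master_seed`; each patient keeps the same simulation noise seed
#' across arms.
#'
#' @param design a [trial_design()].
#' @param progress print per-stage progress?
#' @return List with `endpoints` (the endpoint table: `network_id`, `arm`,
#'   `region`, `raw_count`, `normalized_count`), `report` (a
#'   `trial_result`), `manifest` (sampled-patient manifest),
#'   `assignments`, `control_result` and `meta` (simulation bookkeeping).
#' @export
run_trial <- function(design = trial_design(), progress = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  seeds <- derive_seeds(design$master_seed, design$n_patients)
  say <- function(...) if (progress) message(...)

  control <- build_control_network(weights = design$weights)
  cohort_sp <- design$cohort
  cohort_sp$seed <- seeds$cohort
  say("generating cohort of ", cohort_sp$n_networks, " networks")
  cohort <- generate_cohort(cohort_sp, control)
  patients <- sample_patients(cohort, design$n_patients,
                              seed = seeds$sampling)
  assignments <- assign_arms(patients, design$mode, design$ratio,
                             seed = seeds$assignment)

  program <- make_ec_program(duration = design$engine$duration_ms,
                             theta_frequency = design$theta_frequency,
                             burst_size = design$burst_size,
                             intra_burst_frequency =
                               design$intra_burst_frequency,
                             dt = design$engine$dt_ms)
  say("control reference run")
  control_result <- run_simulation(control, program, seed = seeds$control,
                                   engine = design$engine)

  by_id <- stats::setNames(patients,
                           vapply(patients, `[[`, character(1),
                                  "network_id"))
  pat_seed <- stats::setNames(seeds$patients[seq_along(patients)],
                              names(by_id))
  rows <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    id <- assignments$network_id[i]
    arm <- assignments$arm[i]
    say("simulating ", id, " / ", arm)
    th <- therapy_spec(arm, memantine_level = design$memantine_level,
                       dbs_frequency = design$dbs_frequency)
    applied <- apply_therapy(by_id[[id]]$network, program, th)
    res <- run_simulation(applied$network, applied$program,
                          seed = pat_seed[[id]], engine = design$engine)
    res <- normalize_counts(res, control_result)
    rows[[i]] <- data.frame(
      network_id = id, arm = arm, region = names(res$region_counts),
      raw_count = as.integer(res$region_counts),
      normalized_count = as.numeric(res$normalized_counts),
      stringsAsFactors = FALSE)
  }
  endpoints <- do.call(rbind, rows)
  rownames(endpoints) <- NULL
  endpoints$arm <- factor(endpoints$arm, levels = TRIAL_ARMS)
  endpoints$arm <- as.character(endpoints$arm)

  report <- trial_report(endpoints)
  list(endpoints = endpoints, report = report,
       manifest = cohort_manifest(patients), assignments = assignments,
       control_result = control_result,
       meta = list(master_seed = design$master_seed,
                   n_cohort = cohort_sp$n_networks,
                   n_patients = design$n_patients,
                   n_endpoint_simulations = nrow(assignments),
                   n_normalization_runs = 1L,
                   arms = TRIAL_ARMS))
}
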