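#' Pathology specification for one virtual AD patient
#'
#' AD is modeled as progressive loss of perforant-path (EC2) projections
#' onto DG granule cells, CA3 pyramidal cells and the hippocampal
#' interneurons, combined with an excitotoxicity drive (raised `power_b`)
#' on the surviving EC2 synapses.
#'
#' @param severity fraction of eligible EC2 projections disabled, in
#'   `[0, 1]`.
#' @param excitotoxicity_level one of 9, 56.7, 63, 135.
#' @param stage `"moderate"` or `"severe"` (bookkeeping label).
#' @return A `pathology_spec` list.
#' @export
pathology_spec <- function(severity, excitotoxicity_level = 9,
                           stage = c("moderate", "severe")) {
  if (!is.numeric(severity) || severity < 0 || severity > 1) {
    stop("severity must lie in [0, 1]")
  }
  if (!any(abs(excitotoxicity_level - EXCITOTOXICITY_LEVELS) < 1e-9)) {
    stop("excitotoxicity level must be one of ",
         paste(EXCITOTOXICITY_LEVELS, collapse = ", "))
  }
  structure(list(severity = severity,
                 excitotoxicity_level = excitotoxicity_level,
                 stage = match.arg(stage)),
            class = "pathology_spec")
}

PATHOLOGY_CLASSES <- c("EC2_granule", "EC2_CA3_pyr", "EC2_interneuron")

eligible_edges <- function(network) {
  which(network$connections$class %in% PATHOLOGY_CLASSES)
}

#' Apply AD pathology to the control network
#'
#' Disables `ceiling(severity * E)` of the E eligible EC2 connections
#' (uniformly sampled with `seed`; for a fixed seed the disabled sets are
#' nested across severities, i.e. loss is progressive) and switches every
#' remaining excitatory EC2 synapse into excitotoxic mode at
#' `spec$excitotoxicity_level`. Population sizes and the connection table
#' layout are unchanged: pathology only flips `enabled` flags and synapse
#' regulation parameters.
#'
#' @param network the control `network_spec`.
#' @param spec a [pathology_spec()].
#' @param seed integer seed for the loss pattern.
#' @return An AD-labeled `network_spec`.
#' @export
apply_ad_pathology <- function(network, spec, seed = 1L) {
  stopifnot(inherits(network, "network_spec"),
            inherits(spec, "pathology_spec"))
  # loss is stratified: each target class is disabled in proportion to
  # severity (progressive loss within every projection class), with a
  # per-class nested permutation so damage accumulates monotonically
  old <- .Random.seed_exists()
  set.seed(seed)
  disabled <- integer(0)
  for (cl in PATHOLOGY_CLASSES) {
    idx <- which(network$connections$class == cl)
    perm <- sample(idx)
    disabled <- c(disabled, perm[seq_len(ceiling(spec$severity *
                                                   length(idx)))])
  }
  .restore_seed(old)
  con <- network$connections
  con$enabled[disabled] <- FALSE
  ec2_exc <- con$source %in% EC2_LINES & con$source_kind == "external" &
    con$kind == "excitatory" & con$enabled
  con$excitotoxic[ec2_exc] <- TRUE
  con$power_b[ec2_exc] <- spec$excitotoxicity_level
  network$connections <- con
  network$label <- sprintf("AD(%s)", spec$stage)
  network$severity <- spec$severity
  network$excitotoxicity_level <- spec$excitotoxicity_level
  network
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Cohort specification
#'
#' @param n_networks number of virtual patients to generate (100 in the
#'   study design).
#' @param prop_moderate proportion of moderate-stage networks (rest are
#'   severe).
#' @param severity_moderate,severity_severe severity ranges per stage.
#' @param levels_moderate,levels_severe candidate excitotoxicity levels per
#'   stage (sampled uniformly per network).
#' @param seed master seed for cohort generation.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_networks = 100, prop_moderate = 0.5,
                        severity_moderate = c(0.30, 0.55),
                        severity_severe = c(0.55, 0.85),
                        levels_moderate = c(56.7, 63),
                        levels_severe = c(63, 135),
                        seed = 1L) {
  stopifnot(n_networks >= 1, prop_moderate >= 0, prop_moderate <= 1,
            all(severity_moderate >= 0), all(severity_severe <= 1))
  structure(list(n_networks = as.integer(n_networks),
                 prop_moderate = prop_moderate,
                 severity_moderate = severity_moderate,
                 severity_severe = severity_severe,
                 levels_moderate = levels_moderate,
                 levels_severe = levels_severe,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate the cohort of virtual AD patients
#'
#' Produces `n_networks` AD networks with stage-stratified severities
#' (uniform within each stage's range) and excitotoxicity levels. All
#' members are pairwise distinct in (disabled-connection set,
#' excitotoxicity level); deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param control optionally, a prebuilt control `network_spec`.
#' @return A `cohort` object: list of members, each with `network_id`,
#'   `stage`, `severity`, `excitotoxicity_level`, `pathology_seed`,
#'   `network` (the AD `network_spec`) and `spec` (the
#'   [pathology_spec()]).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            control = build_control_network()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_networks
  n_mod <- round(spec$prop_moderate * n)
  stages <- c(rep("moderate", n_mod), rep("severe", n - n_mod))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  members <- vector("list", n)
  seen <- character(0)
  n_eligible <- length(eligible_edges(control))
  for (i in seq_len(n)) {
    for (attempt in 1:1000) {
      stage <- stages[i]
      rng <- if (stage == "moderate") spec$severity_moderate else
        spec$severity_severe
      lv <- if (stage == "moderate") spec$levels_moderate else
        spec$levels_severe
      sev <- stats::runif(1, rng[1], rng[2])
      level <- sample(lv, 1)
      pseed <- sample.int(.Machine$integer.max, 1)
      ps <- pathology_spec(sev, level, stage)
      net <- apply_ad_pathology(control, ps, seed = pseed)
      key <- paste(level,
                   paste(which(!net$connections$enabled), collapse = ","))
      if (!(key %in% seen)) break
      if (attempt == 1000) {
        stop("cohort generation: could not find ", n,
             " distinct networks in the combinatorial space")
      }
    }
    seen <- c(seen, key)
    members[[i]] <- list(network_id = sprintf("N%03d", i), stage = stage,
                         severity = sev, excitotoxicity_level = level,
                         pathology_seed = pseed, network = net, spec = ps)
  }
  .restore_seed(old)
  structure(members, class = "cohort")
}

#' Sample trial patients from the cohort
#'
#' Uniform sampling without replacement; deterministic given `seed`.
#'
#' @param cohort a `cohort`.
#' @param n number of patients (<= cohort size).
#' @param seed integer seed.
#' @return A `cohort` containing the sampled members.
#' @export
sample_patients <- function(cohort, n = 20, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (n > length(cohort)) {
    stop("cannot sample ", n, " patients from a cohort of ", length(cohort))
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  idx <- sample.int(length(cohort), n)
  .restore_seed(old)
  structure(cohort[idx], class = "cohort")
}

#' Cohort manifest table
#'
#' @param cohort a `cohort`.
#' @return data.frame with one row per member: `network_id`, `stage`,
#'   `severity`, `excitotoxicity_level`, `pathology_seed`,
#'   `n_disabled`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort, function(m) {
    data.frame(network_id = m$network_id, stage = m$stage,
               severity = m$severity,
               excitotoxicity_level = m$excitotoxicity_level,
               pathology_seed = m$pathology_seed,
               n_disabled = sum(!m$network$connections$enabled),
               stringsAsFactors = FALSE)
  }))
}
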