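test_that("severity 0 at level 9 reproduces the control connection table", {
  net <- build_control_network()
  ad <- apply_ad_pathology(net, pathology_spec(0, 9, "moderate"), seed = 1)
  expect_true(all(ad$connections$enabled))
  expect_equal(ad$connections$power_b, net$connections$power_b)
  # behavioral identity under the same stimulus and seed
  prog <- make_ec_program(duration = 1000)
  r_ctl <- run_simulation(net, prog, seed = 2, engine = fast_engine())
  ad$label <- "control"  # compare like for like in metadata-free terms
  r_ad <- run_simulation(ad, prog, seed = 2, engine = fast_engine())
  expect_identical(r_ctl$spike_trains, r_ad$spike_trains)
})

test_that("severity disables ceiling(s * E_class) edges per target class,
           nested across severities, and spares other pathways", {
  net <- build_control_network()
  con <- net$connections
  classes <- c("EC2_granule", "EC2_CA3_pyr", "EC2_interneuron")
  eligible <- con$class %in% classes

  ad_half <- apply_ad_pathology(net, pathology_spec(0.5, 63, "moderate"),
                                seed = 4)
  for (cl in classes) {
    expect_equal(sum(!ad_half$connections$enabled[con$class == cl]),
                 ceiling(0.5 * sum(con$class == cl)))
  }

  ad_full <- apply_ad_pathology(net, pathology_spec(1, 63, "severe"),
                                seed = 4)
  expect_true(all(!ad_full$connections$enabled[eligible]))
  expect_true(all(ad_full$connections$enabled[!eligible]))

  # nestedness for a fixed seed
  sets <- lapply(c(0.2, 0.4, 0.6, 0.8), function(s) {
    ad <- apply_ad_pathology(net, pathology_spec(s, 63, "moderate"),
                             seed = 4)
    which(!ad$connections$enabled)
  })
  for (k in 2:4) expect_true(all(sets[[k - 1]] %in% sets[[k]]))

  # surviving excitatory EC2 synapses switch to excitotoxic mode
  surv <- ad_half$connections
  ec2 <- surv$source %in% paste0("Ex", 1:9) & surv$kind == "excitatory"
  expect_true(all(surv$excitotoxic[ec2 & surv$enabled]))
  expect_true(all(surv$power_b[ec2 & surv$enabled] == 63))
  expect_false(any(surv$excitotoxic[!ec2]))

  expect_error(apply_ad_pathology(net, pathology_spec(1.2, 63)), "\\[0, 1\\]")
})

test_that("cohort generation: distinct members, stage mixture,
           determinism", {
  spec <- cohort_spec(n_networks = 30, seed = 11)
  coh <- generate_cohort(spec)
  expect_length(coh, 30)
  man <- cohort_manifest(coh)
  expect_equal(sum(man$stage == "moderate"), 15)
  expect_true(all(man$severity[man$stage == "moderate"] >= 0.30 &
                    man$severity[man$stage == "moderate"] <= 0.55))
  expect_true(all(man$excitotoxicity_level[man$stage == "severe"] %in%
                    c(63, 135)))
  # pairwise distinctness of (disabled set, level)
  keys <- vapply(coh, function(m) {
    paste(m$excitotoxicity_level,
          paste(which(!m$network$connections$enabled), collapse = ","))
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  # determinism / seed sensitivity
  coh2 <- generate_cohort(cohort_spec(n_networks = 30, seed = 11))
  expect_identical(cohort_manifest(coh2), man)
  coh3 <- generate_cohort(cohort_spec(n_networks = 30, seed = 12))
  expect_false(identical(cohort_manifest(coh3), man))
})

test_that("patient sampling is uniform without replacement and
           reproducible", {
  coh <- generate_cohort(cohort_spec(n_networks = 25, seed = 2))
  s1 <- sample_patients(coh, 10, seed = 5)
  s2 <- sample_patients(coh, 10, seed = 5)
  ids <- vapply(s1, `[[`, character(1), "network_id")
  expect_length(unique(ids), 10)
  expect_identical(ids, vapply(s2, `[[`, character(1), "network_id"))
  all20 <- sample_patients(coh, 25, seed = 1)
  expect_setequal(vapply(all20, `[[`, character(1), "network_id"),
                  vapply(coh, `[[`, character(1), "network_id"))
  expect_error(sample_patients(coh, 26, seed = 1), "cohort")
})

test_that("expected CA1 spike count is non-increasing along a severity
           ladder", {
  # level 9 isolates the synaptic-loss axis (excitotoxic drive is the
  # orthogonal disease axis). Loss of EC2->interneuron edges can
  # disinhibit a single realization, so the monotone-degeneration
  # property is asserted on the loss-pattern-averaged response.
  net <- build_control_network()
  prog <- make_ec_program(duration = 1000)
  ca1 <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    mean(vapply(1:5, function(e) {
      ad <- apply_ad_pathology(net, pathology_spec(s, 9, "moderate"),
                               seed = e)
      r <- run_simulation(ad, prog, seed = 3, engine = fast_engine())
      unname(r$region_counts["CA1"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ca1) <= 0))
  expect_lt(ca1[5], ca1[1])
})
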