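test_that("control network has the prescribed populations and wiring", {
  net <- build_control_network()
  sizes <- setNames(net$populations$size, net$populations$name)
  expect_equal(unname(sizes["CA3_pyramidal"]), 16L)
  expect_equal(unname(sizes["DG_granule"]), 8L)
  expect_equal(unname(sizes["CA1_pyramidal"]), 8L)
  expect_equal(sum(sizes[c("DG_basket", "CA3_basket", "CA1_basket")]), 6L)
  expect_equal(sum(sizes[c("CA3_OLM", "CA1_OLM")]), 2L)
  expect_gte(unname(sizes["DG_mossy"]), 1L)
  expect_equal(nrow(net$cells), sum(sizes))

  con <- net$connections
  expect_true(all(con$enabled))
  # every CA3 pyramidal cell receives basket and O-LM inhibition
  for (p in paste0("CA3_P", 1:16)) {
    src <- con$source[con$target == p & con$kind == "inhibitory"]
    expect_true(any(src %in% c("B3", "B4")))
    expect_true("OLM1" %in% src)
  }
  # inhibition originates only from basket, O-LM, or septal sources
  inh_src <- unique(con$source[con$kind == "inhibitory"])
  expect_true(all(inh_src %in% c(paste0("B", 1:6), "OLM1", "OLM2",
                                 paste0("T", 1:9))))
  # construction is deterministic
  expect_identical(net$connections, build_control_network()$connections)
})

test_that("single-compartment neuron follows the closed-form RC solution", {
  p <- neuron_params(tau_m = 20, n_compartments = 1)
  st <- neuron_rest_state(p)
  drive <- 0.35   # mV/ms, subthreshold steady drive
  v <- numeric(60)
  for (t in 1:60) {
    out <- advance_neuron(st, drive, dt = 1, params = p, substeps = 100L)
    st <- out$state
    v[t] <- st$v[1]
    expect_false(out$spiked)
  }
  closed <- -80 + drive * 20 * (1 - exp(-(1:60) / 20))
  expect_equal(v, closed, tolerance = 1e-3)
})

test_that("neuron at rest with zero drive is a fixed point; suprathreshold
           drive spikes no faster than the refractory period allows", {
  p <- neuron_params()
  st <- neuron_rest_state(p)
  for (t in 1:20) {
    out <- advance_neuron(st, rep(0, 16), dt = 1, params = p)
    st <- out$state
  }
  expect_equal(st$v, rep(-80, 16))

  st <- neuron_rest_state(p)
  spikes <- integer(0)
  for (t in 1:200) {
    out <- advance_neuron(st, c(15, rep(0, 15)), dt = 1, params = p)
    st <- out$state
    if (out$spiked) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 3)
  expect_true(all(diff(spikes) >= p$refractory))
  expect_error(advance_neuron(st, c(NaN, rep(0, 15)), 1, p), "finite")
})

test_that("a network with silent external lines produces no spikes", {
  net <- build_control_network()
  prog <- make_ec_program(duration = 1000, septal = FALSE)
  prog$events <- prog$events[0, ]   # silence every line
  res <- run_simulation(net, prog, seed = 1, engine = fast_engine())
  expect_equal(nrow(res$spike_trains), 0L)
  expect_equal(unname(res$region_counts), c(0L, 0L, 0L))
})

test_that("identical (network, program, seed) yield bit-identical spike
           trains; counts match an independent recount", {
  net <- build_control_network()
  prog <- make_ec_program(duration = 1000)
  r1 <- run_simulation(net, prog, seed = 5, engine = fast_engine())
  r2 <- run_simulation(net, prog, seed = 5, engine = fast_engine())
  expect_identical(r1$spike_trains, r2$spike_trains)
  expect_identical(r1$region_counts, r2$region_counts)
  expect_gt(sum(r1$region_counts), 0)

  # recount oracle from the spike_trains field
  cells <- net$cells
  sp <- r1$spike_trains[r1$spike_trains$t_ms >= r1$meta$transient_ms, ]
  for (r in c("DG", "CA3", "CA1")) {
    pc <- cells$cell_id[cells$region == r & cells$principal]
    expect_equal(unname(r1$region_counts[r]), sum(sp$cell_id %in% pc))
  }
})

test_that("pathology and therapy conserve topology: sizes and edges are
           never added or removed", {
  net <- build_control_network()
  ad <- apply_ad_pathology(net, pathology_spec(0.6, 63, "severe"), seed = 3)
  expect_identical(ad$populations, net$populations)
  expect_identical(ad$connections[c("source", "target", "target_comp",
                                    "kind", "class")],
                   net$connections[c("source", "target", "target_comp",
                                     "kind", "class")])
  th <- apply_therapy(ad, make_ec_program(duration = 1000),
                      therapy_spec("DBS_memantine"))
  expect_identical(th$network$connections$enabled, ad$connections$enabled)
  expect_identical(th$network$populations, net$populations)
})

test_that("normalization divides by the control counts and rejects silent
           control regions", {
  net <- build_control_network()
  prog <- make_ec_program(duration = 1000)
  ctl <- run_simulation(net, prog, seed = 5, engine = fast_engine())
  self <- normalize_counts(ctl, ctl)
  expect_equal(unname(self$normalized_counts), c(1, 1, 1))

  broken <- ctl
  broken$region_counts["CA1"] <- 0L
  expect_error(normalize_counts(ctl, broken), "CA1")
})
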