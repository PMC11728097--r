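test_that("registers rest at zero and spikes expire after register_length", {
  s <- synapse_state("excitatory", base_weight = 1, nmda_weight = 0.5)
  s1 <- in_ex(s, FALSE)
  expect_identical(s1$e_register, numeric(80))
  expect_identical(s1$m_register, numeric(80))

  s2 <- in_ex(s, TRUE)
  expect_gt(sum(s2$e_register), 0)
  for (i in 1:80) s2 <- in_ex(s2, FALSE)
  expect_identical(s2$e_register, numeric(80))
  expect_identical(s2$m_register, numeric(80))
})

test_that("in_ex rejects inhibitory synapses", {
  s <- synapse_state("inhibitory", base_weight = -1)
  expect_error(in_ex(s, TRUE), "excitatory")
})

test_that("register pipeline equals truncated-kernel convolution on a
           Poisson train", {
  spikes <- poisson_train(400, 0.08)
  expect_gte(sum(spikes), 20)

  # AMPA path: no NMDA machinery, so S = ReP + power * conv(spikes, kernel)
  s <- synapse_state("excitatory", base_weight = 0.7, nmda_weight = 0,
                     power_a = 9)
  trace <- synapse_run(s, spikes)
  oracle <- -80 + 9 * conv_oracle(spikes, 0.7, tau = 5, length = 80)
  expect_equal(as.numeric(trace), oracle, tolerance = 1e-9)

  # NMDA register content follows the slow kernel independently
  s <- synapse_state("excitatory", base_weight = 1e-9, nmda_weight = 0.4)
  for (t in seq_along(spikes)) s <- in_ex(s, spikes[t] == 1L)
  m_oracle <- conv_oracle(spikes, 0.4, tau = 50, length = 80)
  expect_equal(sum(s$m_register), m_oracle[length(spikes)],
               tolerance = 1e-9)

  # GABA path uses its own kernel and a negative weight
  s <- synapse_state("inhibitory", base_weight = -0.5)
  trace <- synapse_run(s, spikes)
  oracle <- -80 + 9 * conv_oracle(spikes, -0.5, tau = 10, length = 80)
  expect_equal(as.numeric(trace), oracle, tolerance = 1e-9)
})

test_that("summarized potential: rest value, hand-summed oracle,
           monotonicity in power", {
  s <- synapse_state("excitatory")
  expect_equal(summarize_potential(s), -80)

  set.seed(1)
  s$e_register <- runif(80, 0, 0.02)   # small: gate stays blocked
  expect_equal(summarize_potential(s), -80 + 9 * sum(s$e_register))

  hot <- apply_excitotoxicity(s, 56.7)
  expect_gt(summarize_potential(hot), summarize_potential(s))

  s$e_register <- runif(80, 0, 0.5)    # large: gate opens, NMDA counts
  s$m_register <- runif(80, 0, 0.3)
  expect_equal(summarize_potential(s),
               -80 + 9 * sum(s$e_register) + sum(s$m_register))

  s$e_register[1] <- NaN
  expect_error(summarize_potential(s), "finite")
})

test_that("NMDA gate honors the threshold and the memantine shift", {
  g <- gating_params(ca_mt = -68)
  expect_equal(nmda_gate(-70, g), "blocked")
  expect_equal(nmda_gate(-60, g), "open")
  g3 <- gating_params(ca_mt = -68, ca_mem = -55)
  expect_equal(nmda_gate(-60, g3), "blocked")
  expect_error(gating_params(ca_mt = -68, ca_mem = -70), "raises")
})

test_that("gate opening triggers LTP; timer decrements and gain resets", {
  s <- synapse_state("excitatory", base_weight = 2, nmda_weight = 1,
                     params = synapse_params(ltp_duration = 5,
                                             ltp_gain = 1.5))
  s <- synapse_step(s, TRUE)   # 9 * 2 = 18 mV above rest: gate open
  expect_true(s$nmda_open)
  expect_equal(s$ltp_timer, 5L)
  expect_equal(s$ltp_gain_active, 1.5)
  timers <- integer(0)
  for (i in 1:20) {
    s <- synapse_step(s, FALSE)
    if (!s$nmda_open) timers <- c(timers, s$ltp_timer)
    if (s$ltp_timer == 0L) break
  }
  # once blocked, the timer falls by exactly 1 per step down to 0
  expect_equal(timers, seq(4L, 0L))
  expect_equal(s$ltp_timer, 0L)
  expect_equal(s$ltp_gain_active, 1)
})

test_that("excitotoxicity accepts only the enumerated levels and is
           pointwise monotone", {
  s <- synapse_state("excitatory", base_weight = 0.1, nmda_weight = 0.2)
  expect_error(apply_excitotoxicity(s, 50), "9, 56.7, 63, 135")

  spikes <- c(rep(c(1, 0), 5), rep(0, 90))
  traces <- lapply(EXCITOTOXICITY_LEVELS, function(lv) {
    as.numeric(synapse_run(apply_excitotoxicity(s, lv), spikes))
  })
  # level 9 equals the control (non-excitotoxic) synapse
  expect_equal(traces[[1]], as.numeric(synapse_run(s, spikes)))
  for (k in 2:4) expect_true(all(traces[[k]] >= traces[[k - 1]] - 1e-12))
})

test_that("NMDA open time is non-increasing in the memantine threshold", {
  spikes <- poisson_train(600, 0.12, seed = 9)
  open_steps <- vapply(c(-68, -65, -63, -55), function(th) {
    s <- synapse_state("excitatory", base_weight = 0.25, nmda_weight = 1,
                       gating = gating_params(ca_mem = th))
    s <- apply_excitotoxicity(s, 63)
    sum(attr(synapse_run(s, spikes), "nmda_open"))
  }, numeric(1))
  expect_gt(open_steps[1], 0)
  expect_true(all(diff(open_steps) <= 0))
  expect_lt(open_steps[4], open_steps[1])
})

test_that("S stays within the boundedness envelope", {
  spikes <- rep(1L, 500)  # one spike every step: worst case
  s <- synapse_state("excitatory", base_weight = 0.3, nmda_weight = 0.4)
  s <- apply_excitotoxicity(s, 135)
  trace <- as.numeric(synapse_run(s, spikes))
  bound <- -80 + 135 * 80 * 1 * 0.3 * 1.5 + 80 * 0.4 * 1.5
  expect_true(all(is.finite(trace)))
  expect_true(all(trace <= bound))
})
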