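test_that("inhibitory gate matches its closed form and is monotone", {
  expect_equal(inhibitory_gate(0), 1)
  expect_equal(inhibitory_gate(200, I_star = 200, gamma = 3), exp(-1))
  expect_equal(inhibitory_gate(400, I_star = 200, gamma = 3), exp(-8))
  x <- seq(0, 600, by = 10)
  g <- inhibitory_gate(x)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g <= 1))
})

test_that("current traces filter the NMDA/GABA currents with their time constants", {
  p <- plasticity_params()
  np <- neuron_params()
  tr <- current_traces(2)
  st <- population_state(2, np)

  # silent network: decay to zero
  tr$E_trace <- c(10, 5); tr$I_trace <- c(3, 8)
  for (i in 1:20000) tr <- update_current_traces(tr, st, p, np, dt = 0.1)
  expect_true(all(tr$E_trace < 1e-6) && all(tr$I_trace < 1e-6))

  # constant conductances: steady state = current magnitude
  st$g_NMDA <- c(1, 2); st$g_GABA <- c(0.5, 1); st$V <- c(-60, -60)
  tr <- current_traces(2)
  for (i in 1:20000) tr <- update_current_traces(tr, st, p, np, dt = 0.1)
  expect_equal(tr$E_trace, st$g_NMDA * (np$V_NMDA - st$V), tolerance = 1e-6)
  expect_equal(tr$I_trace, st$g_GABA * (st$V - np$V_GABA), tolerance = 1e-6)

  # step response of the slow (GABA) filter: 1 - exp(-t/tau) at t = tau
  tr <- current_traces(1)
  st1 <- population_state(1, np); st1$g_GABA <- 1; st1$V <- -60
  n <- round(p$tau_I_curr / 0.1)
  for (i in seq_len(n)) tr <- update_current_traces(tr, st1, p, np, dt = 0.1)
  asym <- st1$g_GABA * (st1$V - np$V_GABA)
  expect_equal(tr$I_trace / asym, 1 - exp(-1), tolerance = 2e-3)
})

test_that("spike traces decay exponentially and increment at the right side", {
  p <- plasticity_params()
  tr <- synaptic_traces(2, 1)
  tr <- update_spike_traces(tr, c(1L, 0L), 0L, p, dt = 0.1)
  expect_equal(tr$x_plus, c(1, 0))
  n <- round(p$tau_plus / 0.1)
  for (i in seq_len(n)) tr <- update_spike_traces(tr, c(0L, 0L), 0L, p, dt = 0.1)
  expect_equal(tr$x_plus[1], exp(-1), tolerance = 1e-10)

  # pre and post spike in the same bin increment their own traces independently
  tr <- synaptic_traces(2, 1)
  tr <- update_spike_traces(tr, c(1L, 1L), 1L, p, dt = 0.1)
  expect_true(all(tr$x_plus > 0) && all(tr$y_minus > 0) && tr$x_isp > 0)
})

test_that("excitatory rule: term-by-term behaviour and gate suppression", {
  p <- plasticity_params()
  n <- 2
  w <- matrix(c(NA, 0.25, 0.25, NA), n, n)  # 1<->2 connected
  tr <- synaptic_traces(n, 1)
  cu <- current_traces(n)
  cu$E_trace <- c(100, 100); cu$I_trace <- c(0, 0)

  # no spikes: unchanged
  expect_equal(apply_excitatory_plasticity(w, tr, c(0L, 0L), cu, p), w)

  # isolated postsynaptic spike with x_plus = 0, y_E = 0: no change
  out <- apply_excitatory_plasticity(w, tr, c(0L, 1L), cu, p)
  expect_equal(out, w)

  # presynaptic spike with y_minus > 0 depresses proportionally to w
  tr2 <- tr; tr2$y_minus <- c(0, 2)
  out <- apply_excitatory_plasticity(w, tr2, c(1L, 0L), cu, p)
  expect_equal(out[1, 2], 0.25 - p$A_LTD * 2 * 0.25)
  expect_equal(out[2, 1], 0.25)   # synapse without a presynaptic spike untouched

  # LTP at a postsynaptic spike with presynaptic trace
  tr3 <- tr; tr3$x_plus <- c(1.5, 0)
  out <- apply_excitatory_plasticity(w, tr3, c(0L, 1L), cu, p)
  expect_equal(out[1, 2], 0.25 + p$A_LTP * 1.5 * 100)

  # gate at I = 2 I* suppresses below 1e-3 of ungated change
  cu2 <- cu; cu2$I_trace <- rep(2 * p$I_star, n)
  out_gated <- apply_excitatory_plasticity(w, tr3, c(0L, 1L), cu2, p)
  expect_lt(abs(out_gated[1, 2] - 0.25),
            1e-3 * abs(out[1, 2] - 0.25))

  # heterosynaptic term depresses all incoming synapses at a post spike
  tr4 <- tr; tr4$y_E <- c(0, 5)
  out <- apply_excitatory_plasticity(w, tr4, c(0L, 1L), cu, p)
  expect_equal(out[1, 2], 0.25 - p$A_het * 5 * 100^2)
})

test_that("inhibitory rule: balance fixed point and sign", {
  p <- plasticity_params(alpha = 1)
  w <- matrix(0.31, 1, 2)
  tr <- synaptic_traces(2, 1)
  tr$x_isp <- 1; tr$y_isp <- c(1, 1)
  cu <- current_traces(2)

  # E = 0: no change regardless of spiking
  cu$E_trace <- c(0, 0); cu$I_trace <- c(50, 50)
  out <- apply_inhibitory_plasticity(w, tr, cu, c(1L, 1L), 1L, p)
  expect_equal(out, w)

  # E = alpha I exactly: fixed point
  cu$E_trace <- c(80, 80); cu$I_trace <- c(80, 80)
  out <- apply_inhibitory_plasticity(w, tr, cu, c(1L, 1L), 1L, p)
  expect_equal(out, w)

  # E > alpha I with coincident spikes strengthens inhibition
  cu$E_trace <- c(120, 120); cu$I_trace <- c(80, 80)
  out <- apply_inhibitory_plasticity(w, tr, cu, c(1L, 1L), 1L, p)
  expect_true(all(out > w))

  # E < alpha I weakens inhibition (clipped at zero)
  cu$E_trace <- c(40, 40); cu$I_trace <- c(80, 80)
  out <- apply_inhibitory_plasticity(w, tr, cu, c(1L, 1L), 1L, p)
  expect_true(all(out < w) && all(out >= 0))
})

test_that("as-printed drive terms swap which side's history each trace carries", {
  p_prose <- plasticity_params()
  p_lit <- plasticity_params(traces_as_printed = TRUE)
  n <- 2
  w <- matrix(c(NA, 0.25, 0.25, NA), n, n)
  cu <- current_traces(n); cu$E_trace <- c(100, 100)
  tr <- synaptic_traces(n, 1)
  tr$x_plus <- c(2, 0)   # neuron 1 has the only tau_plus history
  # prose: post spike of neuron 2 potentiates 1->2 via x_plus[1]
  out_p <- apply_excitatory_plasticity(w, tr, c(0L, 1L), cu, p_prose)
  expect_gt(out_p[1, 2], 0.25)
  # literal equations: the same event reads the postsynaptic neuron's history
  out_l <- apply_excitatory_plasticity(w, tr, c(0L, 1L), cu, p_lit)
  expect_equal(out_l[1, 2], 0.25)
})

test_that("parameter constructors validate their invariants", {
  expect_error(neuron_params(tau_m = -1), "time constants")
  expect_error(neuron_params(V_rest = -40), "V_rest")
  expect_error(plasticity_params(gamma = 0.5), "gamma")
  expect_error(plasticity_params(A_LTP = -1), "learning rates")
  expect_error(plasticity_params(alpha = 0), "alpha")
})
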