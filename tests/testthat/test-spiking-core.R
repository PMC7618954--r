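test_that("membrane dynamics have the right fixed points and steady states", {
  p <- neuron_params()
  st <- population_state(3, p)
  out <- integrate_membrane(st, p, dt = 0.1)
  expect_equal(out$state$V, rep(p$V_rest, 3))
  expect_equal(out$spikes, rep(0L, 3))

  # constant AMPA conductance: V converges to the conductance-weighted mean
  g <- 0.25
  st <- population_state(1, p)
  for (i in 1:20000) {
    st$g_AMPA <- g
    st <- integrate_membrane(st, p, dt = 0.1)$state
    if (st$V >= p$V_th) stop("unexpected spike in subthreshold test")
  }
  geff <- g / p$g_L
  v_inf <- (p$V_rest + geff * p$V_AMPA) / (1 + geff)
  expect_lt(v_inf, p$V_th)   # the chosen g keeps the test subthreshold
  expect_equal(st$V, v_inf, tolerance = 1e-6)
})

test_that("threshold crossing resets to rest and clamps for the class refractory period", {
  p <- neuron_params()
  st <- population_state(2, p, V = p$V_th + 1)
  out <- integrate_membrane(st, p, dt = 0.1, class_E = c(TRUE, FALSE))
  expect_equal(out$spikes, c(1L, 1L))
  expect_equal(out$state$V, rep(p$V_rest, 2))
  expect_equal(out$state$refractory_remaining, c(p$tau_ref_E, p$tau_ref_I))
  # clamped at rest for tau_ref even under strong drive
  st <- out$state
  clamped <- 0
  for (i in 1:100) {
    st$g_AMPA <- rep(50, 2)
    st <- integrate_membrane(st, p, dt = 0.1, class_E = c(TRUE, FALSE))$state
    if (st$V[1] == p$V_rest) clamped <- clamped + 1 else break
  }
  expect_gte(clamped * 0.1, p$tau_ref_E - 0.11)
  expect_lte(clamped * 0.1, p$tau_ref_E + 0.31)
})

test_that("membrane potential relaxes to rest within 5 tau_m of silence", {
  p <- neuron_params()
  st <- population_state(4, p, V = c(-52, -60, -75, -79.9))
  n_steps <- round(5 * p$tau_m / 0.1)
  for (i in seq_len(n_steps)) st <- integrate_membrane(st, p, dt = 0.1)$state
  expect_true(all(abs(st$V - p$V_rest) < 0.1))
})

test_that("halving dt changes the free trajectory within the Euler error bound", {
  p <- neuron_params()
  run <- function(dt) {
    st <- population_state(1, p, V = -55)
    for (i in seq_len(round(100 / dt))) st <- integrate_membrane(st, p, dt = dt)$state
    st$V
  }
  v1 <- run(0.1); v2 <- run(0.05)
  exact <- p$V_rest + (-55 - p$V_rest) * exp(-100 / p$tau_m)
  # first-order scheme: error halves with dt
  expect_lt(abs(v2 - exact), abs(v1 - exact))
  expect_lt(abs(v1 - exact), 0.01)
})

test_that("AHP conductance decays exponentially and sums over spikes", {
  p <- neuron_params()
  st <- population_state(1, p)
  st <- update_ahp(st, 0L, p, dt = 0.1)
  expect_equal(st$g_AHP, 0)

  st <- population_state(1, p)
  st <- update_ahp(st, 1L, p, dt = 0.1)
  for (i in seq_len(1000 - 1)) st <- update_ahp(st, 0L, p, dt = 0.1)
  expect_equal(st$g_AHP, p$A_AHP * exp(-1), tolerance = 1e-3)

  st <- population_state(1, p)
  st <- update_ahp(st, 1L, p, dt = 0.1)
  for (i in seq_len(499)) st <- update_ahp(st, 0L, p, dt = 0.1)
  st <- update_ahp(st, 1L, p, dt = 0.1)
  expect_equal(st$g_AHP, p$A_AHP * (1 + exp(-0.5)), tolerance = 2e-3)
})

test_that("synaptic conductances decay and integrate weighted presynaptic spikes", {
  # pure decay
  g <- 1
  for (i in 1:1000) g <- update_conductance(g, 5, 0L, 0.3, dt = 0.1)
  expect_equal(g, exp(-100 / 5), tolerance = 1e-3)

  # a 0.25 nS spike then halving every tau * ln 2
  g <- update_conductance(0, 5, 1L, 0.25, dt = 0.1)
  expect_equal(g, 0.25)
  half_steps <- round(5 * log(2) / 0.1)
  for (i in seq_len(half_steps)) g <- update_conductance(g, 5, 0L, 0.25, dt = 0.1)
  expect_equal(g, 0.125, tolerance = 0.02)  # forward-Euler decay at dt = 0.1

  # linear superposition of simultaneous spikes
  g <- update_conductance(0, 5, c(1L, 1L), matrix(c(0.1, 0.3), 2, 1), dt = 0.1)
  expect_equal(g, 0.4)

  expect_error(update_conductance(0, 5, c(1L, 1L), 0.1), "rows")
  expect_error(update_conductance(0, 5, 1L, -0.1), "non-negative")
})

test_that("poisson_spikes matches Poisson counting statistics and is seed-stable", {
  expect_equal(sum(poisson_spikes(0, 10, duration = 1)), 0)
  set.seed(7)
  n <- sum(poisson_spikes(1, 100, duration = 10))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
  set.seed(11)
  n2 <- sum(poisson_spikes(2.5, 100, duration = 3.3))
  expect_lt(abs(n2 - 825), 3 * sqrt(825))
  set.seed(5)
  a <- poisson_spikes(20, 10, duration = 0.5)
  set.seed(5)
  b <- poisson_spikes(20, 10, duration = 0.5)
  expect_identical(a, b)
  expect_error(poisson_spikes(20000, 1, duration = 1, dt = 0.1), "rate")
})

test_that("conductance non-negativity is preserved by any spike pattern", {
  set.seed(2)
  g <- runif(5)
  for (i in 1:200) {
    sp <- as.integer(runif(3) < 0.3)
    w <- matrix(runif(15, 0, 0.5), 3, 5)
    g <- update_conductance(g, 10, sp, w, dt = 0.1)
    expect_true(all(g >= 0))
  }
})

test_that("raster export writes the two-column tab-separated schema", {
  sp <- tibble::tibble(time_s = c(0.1, 0.2), neuron_id = c(3L, 1001L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_raster(sp, f)
  back <- read.delim(f)
  expect_equal(names(back), c("time_s", "neuron_id"))
  expect_equal(back$neuron_id, c(3L, 1001L))
})
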