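small_config <- function(...) {
  network_config(N_E = 120, N_I = 30, n_background = 20, rate_cap = -1, ...)
}
small_layout <- function(...) {
  assembly_layout(size = 20, i_size = 5, stim_n = 20, settle_s = 0.5, ...)
}

test_that("network construction matches the configured architecture", {
  set.seed(1)
  net <- build_network()
  expect_equal(length(net$state$V_E), 1000)
  expect_equal(length(net$state$V_I), 250)
  expect_named(net$groups, c("ee", "ei", "ie", "ii", "bg"))
  expect_equal(net$groups$ee$plastic, 1L)
  expect_equal(net$groups$ie$plastic, 2L)
  expect_equal(net$groups$ei$plastic, 0L)
  # E-E synapse count: Binomial(1000*999, 0.05)
  n_ee <- length(net$groups$ee$w)
  mu <- 0.05 * 1000 * 999
  expect_lt(abs(n_ee - mu), 3 * sqrt(mu * 0.95))
  expect_false(any(net$groups$ee$pre == net$groups$ee$post))
  # background group: all-to-all onto E
  expect_equal(length(net$groups$bg$w), 100 * 1000)
  expect_error(network_config(p_conn = 0), "p_conn")
})

test_that("assembly embedding draws truncated weights and sets the microcircuit", {
  set.seed(2)
  net <- build_network(small_config())
  net <- embed_assemblies(net, small_layout(), settle = FALSE)
  for (k in 1:6) {
    g <- net$groups[[paste0("stim", k)]]
    expect_true(all(g$w >= 0.07 & g$w <= 0.13))
    expect_equal(length(g$w), 20 * 20)   # stimulus connects with p = 1
  }
  expect_error(embed_assemblies(net, small_layout()), "already embedded")
  # intra-assembly pool weights sit at the strengthened value
  ie <- net$groups$ie
  IM <- net$members$I; EM <- net$members$E
  intra <- ie$pre %in% IM[[1]] & ie$post %in% EM[[1]]
  expect_true(any(intra))
  expect_true(all(ie$w[intra] >= 0.75 & ie$w[intra] <= 1.05))
})

test_that("assembly overlap shares the requested neurons symmetrically", {
  lay <- set_assembly_overlap(assembly_layout(), 0.4)
  m <- spreadnet:::assembly_members(lay)
  for (k in 1:6) {
    nb <- k %% 6 + 1
    expect_equal(length(intersect(m[[k]], m[[nb]])), 40)
  }
  far <- length(intersect(m[[1]], m[[4]]))
  expect_equal(far, 0)
  expect_equal(length(intersect(spreadnet:::assembly_members(assembly_layout())[[1]],
                                spreadnet:::assembly_members(assembly_layout())[[2]])), 0)
  expect_error(set_assembly_overlap(assembly_layout(), 1), "fraction")
})

test_that("ring embedding tags adjacency correctly and refuses 'pre'", {
  set.seed(3)
  net <- build_network(small_config())
  net <- embed_assemblies(net, small_layout(), settle = FALSE)
  expect_warning(net2 <- embed_ring(net, condition_spec("pre")), "no ring stage")
  spec <- condition_spec("plc", learn_s = 0.3, settle_s = 0.1)
  net3 <- embed_ring(net, spec)
  ee <- net3$groups$ee; EM <- net3$members$E
  # ring E-E weights between assemblies 1 and 2 drawn around 0.43
  r12 <- ee$pre %in% EM[[1]] & ee$post %in% EM[[2]]
  if (any(r12)) expect_true(all(ee$w[r12] > 0.3))
  # non-adjacent pairs keep initial-scale weights
  r14 <- ee$pre %in% EM[[1]] & ee$post %in% EM[[4]]
  if (any(r14)) expect_true(all(ee$w[r14] < 0.4))
  # internodal I-to-E index set points at neighbours only
  ie <- net3$groups$ie; IM <- net3$members$I
  idx <- net3$tags$internodal_ie_idx
  expect_true(all(ie$pre[idx] %in% unlist(IM)))
  bad <- ie$pre[idx] %in% IM[[1]] & ie$post[idx] %in% EM[[4]]
  expect_false(any(bad))
})

test_that("disinhibition scales the targeted weights only", {
  set.seed(4)
  net <- build_network(small_config())
  net <- embed_assemblies(net, small_layout(), settle = FALSE)
  net <- embed_ring(net, condition_spec("plc", learn_s = 0.2, settle_s = 0))
  w_ie <- net$groups$ie$w
  w_ei <- net$groups$ei$w
  same <- apply_disinhibition(net, "local", 1)
  expect_equal(same$groups$ie$w, w_ie)
  loc <- apply_disinhibition(net, "local", 0.8)
  idx <- net$tags$internodal_ie_idx
  expect_equal(loc$groups$ie$w[idx], w_ie[idx] * 0.8)
  expect_equal(loc$groups$ie$w[-idx], w_ie[-idx])
  glob <- apply_disinhibition(net, "global", 0.9)
  expect_equal(glob$groups$ei$w, w_ei * 0.9)
  expect_error(apply_disinhibition(net, "local", 0), "scale")
})

test_that("compiled engine matches the plain-R kernel composition", {
  net <- tiny_network()
  n_steps <- 1500   # 150 ms
  ref <- r_engine(net, n_steps, plastic = TRUE)
  cpp <- spreadnet:::run_stage(net, n_steps * net$config$dt / 1000, "xcheck",
                               plastic = TRUE, record = TRUE, rate_cap = -1)
  # same spikes at the same steps
  sp_cpp <- cpp$last_stage$spikes
  step_cpp <- round(sp_cpp$time_s * 1000 / net$config$dt)
  expect_equal(nrow(ref$spikes), nrow(sp_cpp))
  o1 <- order(ref$spikes$step, ref$spikes$id)
  o2 <- order(step_cpp, sp_cpp$neuron_id)
  expect_equal(ref$spikes$step[o1], step_cpp[o2])
  expect_equal(ref$spikes$id[o1], sp_cpp$neuron_id[o2])
  # same membrane state and plastic weights
  expect_equal(ref$V_E, cpp$state$V_E, tolerance = 1e-8)
  expect_equal(ref$V_I, cpp$state$V_I, tolerance = 1e-8)
  expect_equal(ref$net$groups$ee$w, cpp$groups$ee$w, tolerance = 1e-8)
  expect_equal(ref$net$groups$ie$w, cpp$groups$ie$w, tolerance = 1e-8)
  expect_equal(ref$curr$E_trace, cpp$state$E_trace, tolerance = 1e-8)
  expect_equal(ref$curr$I_trace, cpp$state$I_trace, tolerance = 1e-8)
})

test_that("frozen plasticity leaves weights untouched and runs reproducibly", {
  net <- tiny_network(seed = 9)
  w0 <- net$groups$ee$w
  out1 <- spreadnet:::run_stage(net, 0.3, "frozen", plastic = FALSE,
                                record = TRUE, rate_cap = -1)
  expect_identical(out1$groups$ee$w, w0)
  out2 <- spreadnet:::run_stage(net, 0.3, "frozen", plastic = FALSE,
                                record = TRUE, rate_cap = -1)
  expect_identical(out1$last_stage$spikes, out2$last_stage$spikes)
})

test_that("full small protocol is seed-deterministic and refractory-consistent", {
  lay <- small_layout()
  spec <- condition_spec("plc", learn_s = 0.5, settle_s = 0.2, baseline_s = 0.5,
                         probe_s = 0.8)
  r1 <- run_full_protocol("plc", config = small_config(), layout = lay,
                          spec = spec, seed = 11)
  r2 <- run_full_protocol("plc", config = small_config(), layout = lay,
                          spec = spec, seed = 11)
  expect_identical(r1$spikes, r2$spikes)
  # inter-spike intervals respect the class refractory periods
  sp <- r1$spikes
  p <- r1$network$nparams
  for (id in unique(sp$neuron_id[sp$neuron_id < 120])[1:10]) {
    tt <- sort(sp$time_s[sp$neuron_id == id])
    if (length(tt) > 1) expect_gte(min(diff(tt)) * 1000, p$tau_ref_E - 1e-9)
  }
  iid <- unique(sp$neuron_id[sp$neuron_id >= 120 & sp$neuron_id < 150])
  for (id in utils::head(iid, 5)) {
    tt <- sort(sp$time_s[sp$neuron_id == id])
    if (length(tt) > 1) expect_gte(min(diff(tt)) * 1000, p$tau_ref_I - 1e-9)
  }
})

test_that("probe restores the stimulus weights and snapshots carry the change", {
  set.seed(12)
  net <- build_network(small_config())
  net <- embed_assemblies(net, small_layout(), settle = FALSE)
  w_stim <- net$groups$stim1$w
  spec <- condition_spec("plc", baseline_s = 0.3, probe_s = 0.3)
  res <- probe_assembly(net, 1, spec, plastic = FALSE)
  expect_equal(res$network$groups$stim1$w, w_stim)
  expect_equal(res$snapshots$before$ee, res$snapshots$after$ee)  # frozen probe
  expect_error(probe_assembly(net, 9, spec), "assembly_id")
})
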