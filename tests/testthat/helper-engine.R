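# A plain-R re-implementation of the engine's step loop, composed from the
# package's exported kernels. Used to cross-validate the compiled engine on
# tiny deterministic networks (no Poisson input; dynamics seeded through
# initial membrane potentials).

dense_from_group <- function(g, n_pre, n_post) {
  m <- matrix(NA_real_, n_pre, n_post)
  m[cbind(g$pre + 1L, g$post + 1L)] <- g$w
  m
}

group_from_dense <- function(g, m) {
  g$w <- m[cbind(g$pre + 1L, g$post + 1L)]
  g
}

# advance a spiking_network by `n_steps` in pure R; returns updated net plus
# a spike log (step, id). Inputs must have rate 0.
r_engine <- function(net, n_steps, plastic = TRUE) {
  np <- net$nparams; pp <- net$pparams
  dt <- net$config$dt
  nE <- net$config$N_E; nI <- net$config$N_I
  stopifnot(all(vapply(net$inputs, function(i) i$rate_hz, numeric(1)) == 0))
  W <- lapply(net$groups, function(g) {
    n_pre <- if (g$pre_type == 2) length(g$pre_ptr) - 1L else if (g$pre_type == 0) nE else nI
    n_post <- if (g$post_type == 0) nE else nI
    dense_from_group(g, n_pre, n_post)
  })
  st <- net$state
  E_state <- structure(list(V = st$V_E, g_AHP = st$g_AHP_E, g_AMPA = st$g_AMPA_E,
                            g_GABA = st$g_GABA_E, g_NMDA = st$g_NMDA_E,
                            refractory_remaining = st$ref_E),
                       class = "population_state")
  I_state <- structure(list(V = st$V_I, g_AHP = st$g_AHP_I, g_AMPA = st$g_AMPA_I,
                            g_GABA = st$g_GABA_I, g_NMDA = st$g_NMDA_I,
                            refractory_remaining = st$ref_I),
                       class = "population_state")
  traces <- synaptic_traces(nE, nI)
  traces$x_plus <- st$x_plus; traces$y_minus <- st$y_minus; traces$y_E <- st$y_E
  traces$y_isp <- st$y_isp; traces$x_isp <- st$x_isp
  curr <- current_traces(nE)
  curr$E_trace <- st$E_trace; curr$I_trace <- st$I_trace
  prev_E <- integer(nE); prev_I <- integer(nI)
  log_step <- integer(0); log_id <- integer(0)

  for (step in seq_len(n_steps)) {
    # decay + delivery (engine step 1-2); AHP increments use previous spikes
    E_state <- decay_deliver_states(E_state, 0L, net, W, prev_E, prev_I, np, dt)
    I_state <- decay_deliver_states(I_state, 1L, net, W, prev_E, prev_I, np, dt)
    E_state <- update_ahp(E_state, prev_E, np, dt)
    if (np$ahp_inhibitory) I_state <- update_ahp(I_state, prev_I, np, dt)
    else I_state$g_AHP <- I_state$g_AHP * (1 - dt / np$tau_AHP)
    outE <- integrate_membrane(E_state, np, dt, class_E = TRUE)
    outI <- integrate_membrane(I_state, np, dt, class_E = FALSE)
    E_state <- outE$state; I_state <- outI$state
    cur_E <- outE$spikes; cur_I <- outI$spikes
    if (plastic) {
      for (k in seq_along(net$groups)) {
        g <- net$groups[[k]]
        if (g$plastic == 1L) {
          W[[k]] <- apply_excitatory_plasticity(W[[k]], traces, cur_E, curr, pp)
        } else if (g$plastic == 2L) {
          W[[k]] <- apply_inhibitory_plasticity(W[[k]], traces, curr,
                                                cur_E, cur_I, pp)
        }
      }
    }
    traces <- update_spike_traces(traces, cur_E, cur_I, pp, dt)
    curr <- update_current_traces(curr, E_state, pp, np, dt)
    ids <- c(which(cur_E == 1L) - 1L, nE + which(cur_I == 1L) - 1L)
    if (length(ids)) {
      log_step <- c(log_step, rep(step, length(ids)))
      log_id <- c(log_id, ids)
    }
    prev_E <- cur_E; prev_I <- cur_I
  }
  for (k in seq_along(net$groups)) net$groups[[k]] <- group_from_dense(net$groups[[k]], W[[k]])
  list(net = net, V_E = E_state$V, V_I = I_state$V,
       spikes = data.frame(step = log_step, id = log_id),
       E_state = E_state, I_state = I_state, traces = traces, curr = curr)
}

decay_deliver_states <- function(state, which_post, net, W, prev_E, prev_I, np, dt) {
  n <- length(state$V)
  gM_in <- numeric(n); gG_in <- numeric(n)
  for (k in seq_along(net$groups)) {
    g <- net$groups[[k]]
    if (g$post_type != which_post) next
    sp <- if (g$pre_type == 0) prev_E else if (g$pre_type == 1) prev_I else next
    if (!any(sp == 1L)) next
    wmat <- W[[k]]; wmat[is.na(wmat)] <- 0
    inc <- drop(crossprod(wmat, sp))
    if (g$pre_type == 0) gM_in <- gM_in + inc else gG_in <- gG_in + inc
  }
  f <- np$nmda_fraction
  state$g_NMDA <- state$g_NMDA * (1 - dt / np$tau_NMDA) + f * gM_in
  state$g_AMPA <- state$g_AMPA * (1 - dt / np$tau_AMPA) + gM_in
  state$g_GABA <- state$g_GABA * (1 - dt / np$tau_GABA) + gG_in
  state
}

# a small network with silent inputs and seeded initial potentials
tiny_network <- function(n_E = 10, n_I = 3, seed = 42, v_kick = 8) {
  set.seed(seed)
  cfg <- network_config(N_E = n_E, N_I = n_I, p_conn = 0.5,
                        n_background = 2, background_rate = 0, rate_cap = -1)
  net <- build_network(cfg, neuron_params(), plasticity_params())
  net$state$V_E <- net$nparams$V_rest + stats::runif(n_E, 0, v_kick + 8)
  net$state$V_I <- net$nparams$V_rest + stats::runif(n_I, 0, v_kick)
  net$state$E_trace <- stats::runif(n_E, 50, 150)
  net$state$I_trace <- stats::runif(n_E, 50, 150)
  net
}
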