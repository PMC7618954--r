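#' Network configuration
#'
#' Sizes, connectivity and initial weights of the recurrent network: 1000
#' excitatory and 250 inhibitory neurons, 5% connection probability between
#' and across all groups, and a background group of 100 Poisson neurons at
#' 1 Hz connected to every excitatory neuron.
#'
#' @param N_E,N_I Population sizes.
#' @param p_conn Connection probability for E-E, E-I, I-E and I-I (no
#'   self-connections).
#' @param w_EE_init,w_EI_init,w_IE_init,w_II_init Initial weights (nS);
#'   `w_XY` denotes an X-to-Y connection.
#' @param n_background,background_rate Background Poisson group size and rate
#'   (Hz); connected to E with probability 1 at `w_input`.
#' @param w_input Background input weight (nS).
#' @param dt Integration step (ms).
#' @param rate_cap Mean excitatory rate (Hz over 1 s) above which a settling
#'   stage raises a runaway-excitation error. Applied to non-probe stages.
#'
#' @return A list of class `network_config`.
#' @export
network_config <- function(N_E = 1000, N_I = 250, p_conn = 0.05,
                           w_EE_init = 0.25, w_EI_init = 0.35,
                           w_IE_init = 0.31, w_II_init = 0.31,
                           n_background = 100, background_rate = 1,
                           w_input = 0.1, dt = 0.1, rate_cap = 60) {
  if (!(p_conn > 0 && p_conn <= 1)) stop("p_conn must be in (0, 1]")
  if (any(c(w_EE_init, w_EI_init, w_IE_init, w_II_init, w_input) < 0))
    stop("initial weights must be >= 0")
  stopifnot(N_E >= 1, N_I >= 1, dt > 0)
  structure(list(N_E = N_E, N_I = N_I, p_conn = p_conn,
                 w_EE_init = w_EE_init, w_EI_init = w_EI_init,
                 w_IE_init = w_IE_init, w_II_init = w_II_init,
                 n_background = n_background, background_rate = background_rate,
                 w_input = w_input, dt = dt, rate_cap = rate_cap),
            class = "network_config")
}

#' Assembly layout
#'
#' Describes the six stimulus-driven cell assemblies: independent Poisson
#' groups of 100 neurons firing at 2.5 Hz wired onto disjoint subgroups of
#' 100 excitatory neurons (stimulus weights drawn 0.1 +/- 0.01 nS), each
#' balanced by a dedicated subgroup of 25 inhibitory neurons whose incoming
#' I-to-E synapses are strengthened to 0.9 +/- 0.05 nS. `overlap_frac > 0`
#' makes ring-neighbouring assemblies share `floor(overlap_frac * size)`
#' excitatory neurons, arranged symmetrically around the ring.
#'
#' All "+/-" values are Gaussian standard deviations, truncated at 3 SD and
#' at zero.
#'
#' @param n_assemblies Number of assemblies (ring nodes).
#' @param size Excitatory neurons per assembly.
#' @param i_size Inhibitory neurons per assembly.
#' @param stim_n,stim_rate Stimulus Poisson group size and rate (Hz).
#' @param w_stim,w_stim_sd Stimulus synapse weight mean and SD (nS).
#' @param w_ie_intra,w_ie_intra_sd Intra-assembly I-to-E weight mean and SD.
#' @param p_pool Connection probability of the designated inhibitory pools
#'   onto their (intra- or inter-nodal) target assemblies; the strengthened
#'   microcircuit is denser than the 5% background so the printed weights
#'   can actually balance assembly excitation.
#' @param p_pool_ei Connection probability of an assembly's excitatory
#'   neurons onto its own inhibitory pool (at the standard E-to-I weight):
#'   dense enough that the pool co-activates with its assembly, making the
#'   inter-nodal inhibition stimulus-locked rather than tonic.
#' @param overlap_frac Pairwise overlap fraction between ring neighbours.
#' @param settle_s Duration (s) of the plasticity-on settling stage run after
#'   embedding.
#' @return A list of class `assembly_layout`.
#' @export
assembly_layout <- function(n_assemblies = 6, size = 100, i_size = 25,
                            stim_n = 100, stim_rate = 2.5,
                            w_stim = 0.1, w_stim_sd = 0.01,
                            w_ie_intra = 0.9, w_ie_intra_sd = 0.05,
                            p_pool = 0.08, p_pool_ei = 0.08,
                            overlap_frac = 0, settle_s = 1) {
  if (!(p_pool > 0 && p_pool <= 1)) stop("p_pool must be in (0, 1]")
  if (!(p_pool_ei > 0 && p_pool_ei <= 1)) stop("p_pool_ei must be in (0, 1]")
  if (!(overlap_frac >= 0 && overlap_frac < 1))
    stop("overlap_frac must be in [0, 1)")
  structure(list(n_assemblies = n_assemblies, size = size, i_size = i_size,
                 stim_n = stim_n, stim_rate = stim_rate,
                 w_stim = w_stim, w_stim_sd = w_stim_sd,
                 w_ie_intra = w_ie_intra, w_ie_intra_sd = w_ie_intra_sd,
                 p_pool = p_pool, p_pool_ei = p_pool_ei,
                 overlap_frac = overlap_frac, settle_s = settle_s),
            class = "assembly_layout")
}

#' Set the overlap fraction of an assembly layout
#'
#' Neighbouring assemblies share `floor(fraction * size)` excitatory neurons,
#' arranged symmetrically around the ring.
#'
#' @param layout An [assembly_layout()].
#' @param fraction Overlap fraction in `[0, 1)`.
#' @return The modified layout.
#' @export
set_assembly_overlap <- function(layout, fraction) {
  if (!(fraction >= 0 && fraction < 1)) stop("overlap fraction must be in [0, 1)")
  layout$overlap_frac <- fraction
  layout
}

#' Learning-condition specification
#'
#' Parameters of the ring-embedding (associative learning) stage. Under
#' placebo (`"plc"`) inter-nodal inhibition is strengthened to 0.9 nS; under
#' atomoxetine (`"atx"`) only to 0.7 nS, and the strengthening stage runs
#' with all E-to-I weights scaled to 97% of their value (restored
#' afterwards), modelling reduced inhibitory firing during learning.
#'
#' @param condition One of `"pre"`, `"plc"`, `"atx"`.
#' @param w_ring,w_ring_sd Ring E-E weight mean and SD (nS).
#' @param w_ie_internodal,w_ie_internodal_sd Inter-nodal I-to-E weight mean
#'   and SD (nS); defaults depend on the condition (0.9 PLC, 0.7 ATX).
#' @param ei_scale E-to-I scaling during the strengthening stage (ATX: 0.97).
#' @param probe_w Probe input weight (nS).
#' @param probe_s Probe duration (s).
#' @param baseline_s Pre-probe baseline recording (s).
#' @param learn_s Duration (s) of the strengthening stage (run under the
#'   scaled E-to-I weights when `ei_scale < 1`).
#' @param settle_s Duration (s) of the plasticity-on settling stage run after
#'   the E-to-I weights are restored.
#' @return A list of class `condition_spec`.
#' @export
condition_spec <- function(condition = c("plc", "atx", "pre"),
                           w_ring = 0.43, w_ring_sd = 0.02,
                           w_ie_internodal = NULL, w_ie_internodal_sd = 0.05,
                           ei_scale = NULL,
                           probe_w = 0.5, probe_s = 3.3, baseline_s = 2,
                           learn_s = 1, settle_s = 0.5) {
  condition <- match.arg(condition)
  if (is.null(w_ie_internodal))
    w_ie_internodal <- switch(condition, plc = 0.9, atx = 0.7, pre = NA_real_)
  if (is.null(ei_scale))
    ei_scale <- switch(condition, plc = 1, atx = 0.97, pre = 1)
  if (!(ei_scale > 0 && ei_scale <= 1)) stop("ei_scale must be in (0, 1]")
  stopifnot(probe_s > 0, baseline_s > 0, learn_s > 0, settle_s >= 0)
  structure(list(condition = condition, w_ring = w_ring, w_ring_sd = w_ring_sd,
                 w_ie_internodal = w_ie_internodal,
                 w_ie_internodal_sd = w_ie_internodal_sd,
                 ei_scale = ei_scale, probe_w = probe_w, probe_s = probe_s,
                 baseline_s = baseline_s, learn_s = learn_s,
                 settle_s = settle_s),
            class = "condition_spec")
}

# Gaussian draw with mean m and SD s, truncated at 3 SD and at 0
rtrunc3 <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  x <- stats::rnorm(n, m, s)
  bad <- which(abs(x - m) > 3 * s | x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), m, s)
    bad <- bad[abs(x[bad] - m) > 3 * s | x[bad] < 0]
  }
  x
}

# Build a synapse group in the layout the compiled engine expects.
# pre0/post0 are 0-based neuron indices within their populations.
new_syn_group <- function(pre_type, post_type, n_pre, n_post,
                          pre0, post0, w, plastic,
                          input_index = -1L, role = "generic") {
  o <- order(pre0, post0)
  pre0 <- pre0[o]; post0 <- post0[o]; w <- w[o]
  pre_ptr <- c(0L, cumsum(tabulate(pre0 + 1L, nbins = n_pre)))
  post_order <- order(post0, pre0) - 1L
  post_ptr <- c(0L, cumsum(tabulate(post0 + 1L, nbins = n_post)))
  list(pre_type = as.integer(pre_type), input_index = as.integer(input_index),
       post_type = as.integer(post_type),
       pre = as.integer(pre0), post = as.integer(post0),
       pre_ptr = as.integer(pre_ptr),
       post_order = as.integer(post_order), post_ptr = as.integer(post_ptr),
       w = as.numeric(w), plastic = as.integer(plastic), role = role)
}

sample_bernoulli_pairs <- function(n_pre, n_post, p, no_self = FALSE) {
  hit <- which(stats::runif(n_pre * n_post) < p) - 1L
  pre <- hit %% n_pre
  post <- hit %/% n_pre
  if (no_self) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  list(pre = pre, post = post)
}

#' Build the recurrent network
#'
#' Samples Bernoulli(`p_conn`) connectivity for the E-E, E-I, I-E and I-I
#' groups (no self-connections), sets the initial weights, attaches the
#' background Poisson group to every excitatory neuron, and registers E-E and
#' I-E as plastic (co-dependent excitatory rule and inhibitory rule
#' respectively); E-I and I-I are static. Uses R's RNG: call [set.seed()]
#' first for reproducibility.
#'
#' @param config A [network_config()].
#' @param nparams A [neuron_params()].
#' @param pparams A [plasticity_params()].
#' @return A list of class `spiking_network`.
#' @export
build_network <- function(config = network_config(),
                          nparams = neuron_params(),
                          pparams = plasticity_params()) {
  stopifnot(inherits(config, "network_config"))
  nE <- config$N_E; nI <- config$N_I; p <- config$p_conn
  ee <- sample_bernoulli_pairs(nE, nE, p, no_self = TRUE)
  ei <- sample_bernoulli_pairs(nE, nI, p)
  ie <- sample_bernoulli_pairs(nI, nE, p)
  ii <- sample_bernoulli_pairs(nI, nI, p, no_self = TRUE)
  groups <- list(
    ee = new_syn_group(0, 0, nE, nE, ee$pre, ee$post,
                       rep(config$w_EE_init, length(ee$pre)), 1L, role = "EE"),
    ei = new_syn_group(0, 1, nE, nI, ei$pre, ei$post,
                       rep(config$w_EI_init, length(ei$pre)), 0L, role = "EI"),
    ie = new_syn_group(1, 0, nI, nE, ie$pre, ie$post,
                       rep(config$w_IE_init, length(ie$pre)), 2L, role = "IE"),
    ii = new_syn_group(1, 1, nI, nI, ii$pre, ii$post,
                       rep(config$w_II_init, length(ii$pre)), 0L, role = "II"),
    bg = new_syn_group(2, 0, config$n_background, nE,
                       rep(0:(config$n_background - 1L), each = nE),
                       rep(0:(nE - 1L), times = config$n_background),
                       rep(config$w_input, config$n_background * nE), 0L,
                       input_index = 0L, role = "background")
  )
  inputs <- list(list(n = config$n_background,
                      rate_hz = config$background_rate, role = "background"))
  state <- list(
    V_E = rep(nparams$V_rest, nE), V_I = rep(nparams$V_rest, nI),
    g_AHP_E = numeric(nE), g_AMPA_E = numeric(nE),
    g_GABA_E = numeric(nE), g_NMDA_E = numeric(nE),
    g_AHP_I = numeric(nI), g_AMPA_I = numeric(nI),
    g_GABA_I = numeric(nI), g_NMDA_I = numeric(nI),
    ref_E = numeric(nE), ref_I = numeric(nI),
    E_trace = numeric(nE), I_trace = numeric(nE),
    x_plus = numeric(nE), y_minus = numeric(nE), y_E = numeric(nE),
    y_isp = numeric(nE), x_isp = numeric(nI),
    t_s = 0)
  structure(list(config = config, nparams = nparams, pparams = pparams,
                 state = state, groups = groups, inputs = inputs,
                 layout = NULL, condition = "unlearned",
                 tags = list(), stage_log = list()),
            class = "spiking_network")
}

# Advance the network by one stage; returns the updated network with the
# stage's spikes (tibble) and trace monitors attached as net$last_stage.
run_stage <- function(net, duration_s, stage_name,
                      plastic = TRUE, record = FALSE, record_inputs = FALSE,
                      rate_cap = net$config$rate_cap) {
  out <- sim_stage_cpp(net$state, unname(net$groups), unname(net$inputs),
                       unclass(net$nparams), unclass(net$pparams),
                       duration_s, net$config$dt,
                       plastic, record, record_inputs,
                       if (is.null(rate_cap)) -1 else rate_cap, stage_name)
  net$state <- out$state
  for (k in seq_along(net$groups)) net$groups[[k]]$w <- out$weights[[k]]
  spikes <- tibble::tibble(time_s = out$spike_time, neuron_id = out$spike_id)
  net$last_stage <- list(name = stage_name, spikes = spikes,
                         mean_E_trace = out$mean_E_trace,
                         mean_I_trace = out$mean_I_trace,
                         mean_E2_trace = out$mean_E2_trace,
                         mean_EI_trace = out$mean_EI_trace,
                         avg_E_trace = out$avg_E_trace,
                         avg_I_trace = out$avg_I_trace,
                         start_s = net$state$t_s - duration_s,
                         end_s = net$state$t_s)
  net$stage_log <- c(net$stage_log, list(list(name = stage_name,
                                              start_s = net$state$t_s - duration_s,
                                              end_s = net$state$t_s,
                                              plastic = plastic)))
  net
}

#' Calibrate the current-trace scale
#'
#' The gate level `I_star` and the balance point `alpha` are defined on a
#' unitless current-trace scale left open by the published equations. This routine
#' fixes it once per network, with plasticity frozen, by measuring the
#' time-averaged filtered NMDA and GABA current traces over the assembly
#' neurons during baseline activity and rescaling the two traces onto the
#' gate's scale: the baseline inhibitory trace is placed at
#' `i_level * I_star` (so the gate is partly open in the balanced network
#' and closes as stimulus-driven inhibition rises above baseline, more so
#' the stronger the inhibitory weights), and the excitatory trace at
#' `e_level * I_star` (its own, much smaller dimensionless scale, keeping
#' per-event weight steps small relative to the weights). The balance point
#' `alpha` of the inhibitory rule is then set from the baseline trace
#' moments and refined by bisection until the plasticity-on network
#' reproduces the plasticity-frozen baseline rate (the rule samples
#' currents at spike times, which biases the naive moment estimate).
#'
#' @param net A [build_network()] result, normally with assemblies embedded.
#' @param duration_s Measurement duration (s).
#' @param warmup_s Discarded transient (s) before measuring.
#' @param i_level,e_level Baseline levels of the inhibitory and excitatory
#'   traces as fractions of `I_star`.
#' @return The network with updated plasticity parameters.
#' @export
calibrate_currents <- function(net, duration_s = 2, warmup_s = 1,
                               i_level = 0.7, e_level = 0.002) {
  net <- run_stage(net, warmup_s, "calibration-warmup", plastic = FALSE,
                   record = FALSE, rate_cap = -1)
  net <- run_stage(net, duration_s, "calibration", plastic = FALSE,
                   record = FALSE, rate_cap = -1)
  if (!is.null(net$layout)) {
    idx <- sort(unique(unlist(net$members$E))) + 1L
    mE <- mean(net$last_stage$avg_E_trace[idx])
    mI <- mean(net$last_stage$avg_I_trace[idx])
  } else {
    mE <- net$last_stage$mean_E_trace
    mI <- net$last_stage$mean_I_trace
  }
  if (mE <= 0 || mI <= 0)
    stop("calibration failed: reference current traces are zero (silent network?)")
  rE <- e_level * net$pparams$I_star / mE
  rI <- i_level * net$pparams$I_star / mI
  net$pparams$current_scale_E <- net$pparams$current_scale_E * rE
  net$pparams$current_scale_I <- net$pparams$current_scale_I * rI
  net$state$E_trace <- net$state$E_trace * rE
  net$state$I_trace <- net$state$I_trace * rI
  # initial balance point from the baseline trace moments: the time-averaged
  # drift of the inhibitory rule is ~ <E (E - alpha I)>, zero at
  # alpha = <E^2>/<E I> (not at mean(E)/mean(I): E multiplies its own
  # fluctuations)
  e2 <- net$last_stage$mean_E2_trace
  ei <- net$last_stage$mean_EI_trace
  if (ei > 0) net$pparams$alpha <- (rE / rI) * e2 / ei
  calibrate_balance(net)
}

# Tune the inhibitory rule's balance point so that baseline activity is
# homeostatic: the rule samples currents at spike times, which biases the
# moment-based alpha toward over-inhibition, while too large an alpha strips
# inhibition and ignites the network. Bisect alpha (log scale) until a short
# plasticity-on segment reproduces the plasticity-frozen baseline rate.
calibrate_balance <- function(net, probe_s = 3, band = c(0.9, 1.2),
                              max_iter = 10) {
  ref <- run_stage(net, probe_s, "balance-reference", plastic = FALSE,
                   record = TRUE, rate_cap = -1)
  r_ref <- sum(ref$last_stage$spikes$neuron_id < net$config$N_E) /
    net$config$N_E / probe_s
  if (r_ref <= 0) stop("balance calibration failed: silent baseline")
  rate_ratio <- function(alpha) {
    n2 <- net
    n2$pparams$alpha <- alpha
    out <- tryCatch(
      run_stage(n2, probe_s, "balance-calibration", plastic = TRUE,
                record = TRUE, rate_cap = net$config$rate_cap),
      error = function(e) NULL)
    if (is.null(out)) return(Inf)   # runaway: alpha too large
    r <- sum(out$last_stage$spikes$neuron_id < net$config$N_E) /
      net$config$N_E / probe_s
    r / r_ref
  }
  a <- net$pparams$alpha
  ratio <- rate_ratio(a)
  if (ratio >= band[1] && ratio <= band[2]) return(net)
  if (ratio < 1) {          # over-inhibited: raise alpha to find the bracket
    a_lo <- a
    a_hi <- a
    for (i in 1:8) {
      a_hi <- a_hi * 2
      if (rate_ratio(a_hi) > 1) break
    }
  } else {
    a_hi <- a
    a_lo <- a
    for (i in 1:8) {
      a_lo <- a_lo / 2
      if (rate_ratio(a_lo) < 1) break
    }
  }
  for (i in seq_len(max_iter)) {
    a_mid <- sqrt(a_lo * a_hi)
    ratio <- rate_ratio(a_mid)
    if (ratio >= band[1] && ratio <= band[2]) {
      net$pparams$alpha <- a_mid
      return(net)
    }
    if (ratio < 1) a_lo <- a_mid else a_hi <- a_mid
  }
  net$pparams$alpha <- a_lo   # fall back to the stable (over-inhibited) side
  net
}

# E-neuron membership (0-based) of each assembly under the layout's overlap
assembly_members <- function(layout) {
  m <- floor(layout$overlap_frac * layout$size)
  stride <- layout$size - m
  n_distinct <- layout$n_assemblies * stride
  lapply(seq_len(layout$n_assemblies), function(k) {
    ((k - 1) * stride + 0:(layout$size - 1)) %% n_distinct
  })
}

#' Embed the stimulus-driven cell assemblies
#'
#' Wires six independent Poisson stimulus groups onto their excitatory
#' subgroups (connection probability 1, weights drawn `w_stim +/- w_stim_sd`),
#' strengthens the existing intra-assembly I-to-E synapses to
#' `w_ie_intra +/- w_ie_intra_sd`, and runs a plasticity-on settling stage so
#' the co-dependent rules stabilise the embedding.
#'
#' @param net A [build_network()] result (no assemblies embedded yet).
#' @param layout An [assembly_layout()].
#' @param settle If `FALSE`, skip the settling stage (used by unit tests).
#' @return The network with assemblies embedded.
#' @export
embed_assemblies <- function(net, layout = assembly_layout(), settle = TRUE) {
  stopifnot(inherits(net, "spiking_network"), inherits(layout, "assembly_layout"))
  if (!is.null(net$layout)) stop("assemblies already embedded")
  if (layout$n_assemblies == 0) return(net)
  n_asm <- layout$n_assemblies
  if (n_asm * layout$i_size > net$config$N_I ||
      (layout$size - floor(layout$overlap_frac * layout$size)) * n_asm >
        net$config$N_E)
    stop("assembly layout does not fit the population sizes")
  E_members <- assembly_members(layout)
  I_members <- lapply(seq_len(n_asm), function(k)
    (k - 1) * layout$i_size + 0:(layout$i_size - 1))
  # stimulus Poisson groups, one per assembly, p = 1
  for (k in seq_len(n_asm)) {
    nk <- length(E_members[[k]])
    net$inputs[[length(net$inputs) + 1]] <-
      list(n = layout$stim_n, rate_hz = layout$stim_rate,
           role = paste0("stimulus_", k))
    w <- rtrunc3(layout$stim_n * nk, layout$w_stim, layout$w_stim_sd)
    net$groups[[paste0("stim", k)]] <-
      new_syn_group(2, 0, layout$stim_n, net$config$N_E,
                    rep(0:(layout$stim_n - 1L), each = nk),
                    rep(E_members[[k]], times = layout$stim_n),
                    w, 0L, input_index = length(net$inputs) - 1L,
                    role = paste0("stimulus_", k))
  }
  # assembly microcircuit: each assembly's excitatory neurons drive their
  # dedicated 25-neuron inhibitory pool (so the pool's firing tracks its own
  # assembly), and the pool projects back at the strengthened I-to-E weight
  ie <- net$groups$ie
  pre <- ie$pre; post <- ie$post; w <- ie$w
  ei <- net$groups$ei
  ei_pre <- ei$pre; ei_post <- ei$post; ei_w <- ei$w
  for (k in seq_len(n_asm)) {
    res <- set_pool_synapses(pre, post, w, I_members[[k]], E_members[[k]],
                             function(n) rtrunc3(n, layout$w_ie_intra,
                                                 layout$w_ie_intra_sd),
                             p = layout$p_pool)
    pre <- res$pre; post <- res$post; w <- res$w
    res2 <- set_pool_synapses(ei_pre, ei_post, ei_w,
                              E_members[[k]], I_members[[k]],
                              function(n) rep(net$config$w_EI_init, n),
                              p = layout$p_pool_ei)
    ei_pre <- res2$pre; ei_post <- res2$post; ei_w <- res2$w
  }
  net$groups$ie <- new_syn_group(1, 0, net$config$N_I, net$config$N_E,
                                 pre, post, w, 2L, role = "IE")
  net$groups$ei <- new_syn_group(0, 1, net$config$N_E, net$config$N_I,
                                 ei_pre, ei_post, ei_w, 0L, role = "EI")
  net$layout <- layout
  net$members <- list(E = E_members, I = I_members)
  if (settle && layout$settle_s > 0)
    net <- run_stage(net, layout$settle_s, "assembly-settling", plastic = TRUE)
  net
}


# Set every synapse from a presynaptic pool onto a set of target neurons in a
# triplet group, creating absent synapses (dense pool connectivity). Returns
# the group as plain triplets plus the indices of the set synapses.
set_pool_synapses <- function(pre, post, w, pool, targets, draw, p = 1) {
  drop <- pre %in% pool & post %in% targets
  pre <- pre[!drop]; post <- post[!drop]; w <- w[!drop]
  new_pre <- rep(pool, each = length(targets))
  new_post <- rep(targets, times = length(pool))
  if (p < 1) {
    keep <- stats::runif(length(new_pre)) < p
    new_pre <- new_pre[keep]; new_post <- new_post[keep]
  }
  new_w <- draw(length(new_pre))
  list(pre = c(pre, new_pre), post = c(post, new_post), w = c(w, new_w),
       tag = length(pre) + seq_along(new_pre))
}

ring_neighbours <- function(k, n) c((k - 2) %% n + 1, k %% n + 1)

#' Embed the ring of associations
#'
#' Strengthens all existing E-E synapses between ring-adjacent assemblies to
#' `w_ring +/- w_ring_sd`, sets the inter-nodal I-to-E synapses (from an
#' assembly's inhibitory subgroup onto the excitatory neurons of its ring
#' neighbours) to the condition's value, and runs the strengthening stage --
#' under E-to-I weights scaled by `ei_scale` when below 1 (the atomoxetine
#' regime), restored afterwards -- followed by a plasticity-on settling
#' stage.
#'
#' @param net A network with assemblies embedded.
#' @param spec A [condition_spec()].
#' @return The network after associative learning.
#' @export
embed_ring <- function(net, spec) {
  stopifnot(inherits(net, "spiking_network"), inherits(spec, "condition_spec"))
  if (is.null(net$layout)) stop("embed assemblies before the ring")
  if (spec$condition == "pre") {
    warning("condition 'pre' has no ring stage; network unchanged")
    return(net)
  }
  n_asm <- net$layout$n_assemblies
  EM <- net$members$E; IM <- net$members$I
  ee <- net$groups$ee; ie <- net$groups$ie
  ring_idx <- integer(0)
  for (k in seq_len(n_asm)) {
    for (nb in ring_neighbours(k, n_asm)) {
      idx <- which(ee$pre %in% EM[[k]] & ee$post %in% EM[[nb]])
      ring_idx <- union(ring_idx, idx)
    }
  }
  ee$w[ring_idx] <- rtrunc3(length(ring_idx), spec$w_ring, spec$w_ring_sd)
  net$groups$ee <- ee
  net$tags$ring_ee_idx <- ring_idx
  # inter-nodal inhibition: each assembly's inhibitory pool fully connected
  # onto the excitatory neurons of its two ring neighbours
  pre <- ie$pre; post <- ie$post; w <- ie$w
  internodal_idx <- integer(0)
  for (k in seq_len(n_asm)) {
    for (nb in ring_neighbours(k, n_asm)) {
      res <- set_pool_synapses(pre, post, w, IM[[k]], EM[[nb]],
                               function(n) rtrunc3(n, spec$w_ie_internodal,
                                                   spec$w_ie_internodal_sd),
                               p = net$layout$p_pool)
      pre <- res$pre; post <- res$post; w <- res$w
      internodal_idx <- c(internodal_idx, res$tag)
    }
  }
  # positions shift as pools are rewired; recompute the inter-nodal index set
  in_internodal <- rep(FALSE, length(pre))
  for (k in seq_len(n_asm)) for (nb in ring_neighbours(k, n_asm))
    in_internodal <- in_internodal | (pre %in% IM[[k]] & post %in% EM[[nb]])
  ord <- order(pre, post)
  net$groups$ie <- new_syn_group(1, 0, net$config$N_I, net$config$N_E,
                                 pre, post, w, 2L, role = "IE")
  net$tags$internodal_ie_idx <- which(in_internodal[ord])
  # strengthening stage, under reduced E-to-I drive when ei_scale < 1
  ei_w <- net$groups$ei$w
  if (spec$ei_scale < 1) net$groups$ei$w <- ei_w * spec$ei_scale
  net <- run_stage(net, spec$learn_s,
                   paste0("ring-strengthening-", spec$condition), plastic = TRUE)
  if (spec$ei_scale < 1) net$groups$ei$w <- ei_w
  if (spec$settle_s > 0)
    net <- run_stage(net, spec$settle_s,
                     paste0("ring-settling-", spec$condition), plastic = TRUE)
  net$condition <- spec$condition
  net
}

#' Weaken inhibition after learning
#'
#' `mode = "local"` multiplies only the inter-nodal I-to-E weights by
#' `scale`; `mode = "global"` multiplies all E-to-I weights by `scale`.
#'
#' @param net A post-learning network.
#' @param mode `"local"` or `"global"`.
#' @param scale Multiplier in (0, 1].
#' @return The modified network.
#' @export
apply_disinhibition <- function(net, mode = c("local", "global"), scale) {
  mode <- match.arg(mode)
  if (!(scale > 0 && scale <= 1)) stop("scale must be in (0, 1]")
  if (mode == "local") {
    idx <- net$tags$internodal_ie_idx
    if (is.null(idx)) stop("no inter-nodal synapses tagged: embed the ring first")
    net$groups$ie$w[idx] <- net$groups$ie$w[idx] * scale
  } else {
    net$groups$ei$w <- net$groups$ei$w * scale
  }
  net
}

#' Probe one assembly
#'
#' Records a baseline segment, then raises the probed assembly's stimulus
#' weights to `probe_w` for `probe_s` seconds while recording, then restores
#' them. Weight snapshots are taken before and after the probe. Plasticity is
#' on during the probe by default.
#'
#' @param net A network with assemblies embedded.
#' @param assembly_id Which assembly to drive (1-based).
#' @param spec A [condition_spec()] (supplies probe weight and durations).
#' @param plastic Run the probe with plasticity on?
#' @return A `protocol_result` object; see [assembly_rates()],
#'   [functional_overlap()], [weight_change_matrix()].
#' @export
probe_assembly <- function(net, assembly_id = 1, spec = condition_spec("plc"),
                           plastic = TRUE) {
  stopifnot(inherits(net, "spiking_network"))
  if (is.null(net$layout)) stop("no assemblies to probe")
  n_asm <- net$layout$n_assemblies
  if (!(assembly_id %in% seq_len(n_asm)))
    stop(sprintf("assembly_id must be in 1..%d", n_asm))
  snapshot <- function(n) list(ee = n$groups$ee$w, ie = n$groups$ie$w)
  net <- run_stage(net, spec$baseline_s, "baseline", plastic = plastic,
                   record = TRUE, rate_cap = -1)
  baseline <- net$last_stage
  before <- snapshot(net)
  gname <- paste0("stim", assembly_id)
  w_orig <- net$groups[[gname]]$w
  net$groups[[gname]]$w <- rep(spec$probe_w, length(w_orig))
  net <- run_stage(net, spec$probe_s, "probe", plastic = plastic,
                   record = TRUE, rate_cap = -1)
  probe <- net$last_stage
  net$groups[[gname]]$w <- w_orig
  after <- snapshot(net)
  spikes <- dplyr::bind_rows(
    dplyr::mutate(baseline$spikes, stage = "baseline"),
    dplyr::mutate(probe$spikes, stage = "stimulus"))
  structure(list(
    spikes = spikes,
    windows = list(baseline = c(baseline$start_s, baseline$end_s),
                   stimulus = c(probe$start_s, probe$end_s)),
    snapshots = list(before = before, after = after),
    ee_pre = net$groups$ee$pre, ee_post = net$groups$ee$post,
    members = net$members, n_E = net$config$N_E, n_I = net$config$N_I,
    probe_id = assembly_id, condition = net$condition,
    layout = net$layout, network = net),
    class = "protocol_result")
}

#' Run the full protocol for one condition
#'
#' Build, calibrate, embed assemblies, embed the ring (unless `"pre"`), and
#' probe assembly 1: the three network snapshots of the study. Fully
#' determined by `seed`.
#'
#' @param condition `"pre"`, `"plc"`, `"atx"`, or the post-learning placebo
#'   disinhibition variants `"plc_local_disinhib"` / `"plc_global_disinhib"`.
#' @param config A [network_config()].
#' @param layout An [assembly_layout()].
#' @param spec A [condition_spec()] or `NULL` to use the condition's
#'   defaults.
#' @param nparams,pparams Neuron and plasticity parameters.
#' @param seed Integer seed.
#' @param disinhib_scale Weight multiplier for the disinhibition variants.
#' @param probe_plastic Plasticity on during the probe?
#' @return A `protocol_result`.
#' @export
run_full_protocol <- function(condition = c("pre", "plc", "atx",
                                            "plc_local_disinhib",
                                            "plc_global_disinhib"),
                              config = network_config(),
                              layout = assembly_layout(),
                              spec = NULL,
                              nparams = neuron_params(),
                              pparams = plasticity_params(),
                              seed = 1,
                              disinhib_scale = 0.8,
                              probe_plastic = TRUE) {
  condition <- match.arg(condition)
  base <- if (condition %in% c("pre")) "pre"
          else if (startsWith(condition, "plc")) "plc" else "atx"
  if (is.null(spec)) spec <- condition_spec(base)
  set.seed(seed)
  net <- build_network(config, nparams, pparams)
  net <- embed_assemblies(net, layout, settle = FALSE)
  net <- calibrate_currents(net)
  if (layout$settle_s > 0)
    net <- run_stage(net, layout$settle_s, "assembly-settling", plastic = TRUE)
  if (base != "pre") net <- embed_ring(net, spec)
  if (condition == "plc_local_disinhib")
    net <- apply_disinhibition(net, "local", disinhib_scale)
  if (condition == "plc_global_disinhib")
    net <- apply_disinhibition(net, "global", disinhib_scale)
  res <- probe_assembly(net, 1, spec, plastic = probe_plastic)
  res$seed <- seed
  res
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("<spiking_network> %d E + %d I neurons, %d synapse groups, t = %.2f s\n",
              x$config$N_E, x$config$N_I, length(x$groups), x$state$t_s))
  cat(sprintf("  condition: %s; assemblies: %s\n", x$condition,
              if (is.null(x$layout)) "none" else x$layout$n_assemblies))
  invisible(x)
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> condition %s, probe assembly %d\n",
              x$condition, x$probe_id))
  cat(sprintf("  baseline %.1f-%.1f s, stimulus %.1f-%.1f s, %d spikes recorded\n",
              x$windows$baseline[1], x$windows$baseline[2],
              x$windows$stimulus[1], x$windows$stimulus[2], nrow(x$spikes)))
  invisible(x)
}
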