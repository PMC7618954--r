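#' Inhibitory gate on excitatory plasticity
#'
#' The multiplicative factor `exp(-(I / I_star)^gamma)` that suppresses every
#' excitatory weight change when the postsynaptic neuron's filtered inhibitory
#' current `I` is high. Equals 1 at `I = 0`, `exp(-1)` at `I = I_star`, and is
#' strictly decreasing in `I`.
#'
#' @param I_trace_value Filtered GABA current trace value(s), >= 0.
#' @param I_star Gate level.
#' @param gamma Gate shape (>= 1).
#' @return Gate factor(s) in (0, 1].
#' @export
#' @examples
#' inhibitory_gate(c(0, 200, 400), I_star = 200, gamma = 3)
inhibitory_gate <- function(I_trace_value, I_star = 200, gamma = 3) {
  stopifnot(all(I_trace_value >= 0), I_star > 0, gamma >= 1)
  exp(-(I_trace_value / I_star)^gamma)
}

#' Create empty current traces
#'
#' Per-(excitatory)-neuron low-pass filtered NMDA and GABA current traces that
#' drive the co-dependent rules. Both are kept positive: the NMDA current is
#' inward (the filter integrates its magnitude) and the GABA current outward.
#'
#' @param n Number of neurons.
#' @return List of class `current_traces` with `E_trace` and `I_trace`.
#' @export
current_traces <- function(n) {
  structure(list(E_trace = numeric(n), I_trace = numeric(n)),
            class = "current_traces")
}

#' Update the filtered current traces
#'
#' One Euler step of the first-order filters
#' \deqn{\tau_E dE/dt = -E + s_E \, g_{NMDA}(V_{NMDA}-V), \qquad
#'       \tau_I dI/dt = -I + s_I \, g_{GABA}(V-V_{GABA}),}
#' with the sign conventions making both drives non-negative and the
#' calibration scales `s_E`, `s_I` from [plasticity_params()].
#'
#' @param traces A [current_traces()] object.
#' @param state A [population_state()] supplying `g_NMDA`, `g_GABA` and `V`.
#' @param params A [plasticity_params()].
#' @param nparams A [neuron_params()] supplying the reversal potentials.
#' @param dt Step width (ms).
#' @return The updated traces.
#' @export
update_current_traces <- function(traces, state, params = plasticity_params(),
                                  nparams = neuron_params(), dt = 0.1) {
  I_nmda <- pmax(params$current_scale_E * state$g_NMDA * (nparams$V_NMDA - state$V), 0)
  I_gaba <- pmax(params$current_scale_I * state$g_GABA * (state$V - nparams$V_GABA), 0)
  E <- traces$E_trace + dt / params$tau_E_curr * (-traces$E_trace + I_nmda)
  I <- traces$I_trace + dt / params$tau_I_curr * (-traces$I_trace + I_gaba)
  if (any(E < 0) || any(I < 0))
    stop("negative current trace: sign convention violated (V outside [V_GABA, V_NMDA]?)")
  traces$E_trace <- E
  traces$I_trace <- I
  traces
}

#' Create empty synaptic spike traces
#'
#' Per-neuron exponentially-decaying traces of the spike trains used by the
#' learning rules: `x_plus` (presynaptic, tau_plus), `y_minus` (postsynaptic,
#' tau_minus), `y_E` (postsynaptic, tau_yE) for the excitatory rule and
#' `x_isp` (presynaptic inhibitory), `y_isp` (postsynaptic) for the inhibitory
#' rule (both tau_STDP).
#'
#' @param n_E Number of excitatory neurons.
#' @param n_I Number of inhibitory neurons.
#' @return List of class `synaptic_traces`.
#' @export
synaptic_traces <- function(n_E, n_I) {
  structure(list(
    x_plus = numeric(n_E), y_minus = numeric(n_E), y_E = numeric(n_E),
    x_isp = numeric(n_I), y_isp = numeric(n_E)
  ), class = "synaptic_traces")
}

#' Update the synaptic spike traces
#'
#' Exact exponential decay over one step followed by unit increments at this
#' step's spikes. Under the default convention each trace is driven by the
#' spikes of the neuron it is attached to (presynaptic traces by presynaptic
#' spikes, postsynaptic by postsynaptic); `traces_as_printed = TRUE` swaps the
#' drive terms so that the literal printed trace equations are reproduced
#' (reading a "presynaptic" trace then returns the postsynaptic neuron's spike
#' history and vice versa).
#'
#' @param traces A [synaptic_traces()] object.
#' @param spikes_E,spikes_I 0/1 spike indicators for the excitatory and
#'   inhibitory populations this step.
#' @param params A [plasticity_params()].
#' @param dt Step width (ms).
#' @return The updated traces.
#' @export
update_spike_traces <- function(traces, spikes_E, spikes_I,
                                params = plasticity_params(), dt = 0.1) {
  d <- function(x, tau) x * exp(-dt / tau)
  traces$x_plus  <- d(traces$x_plus,  params$tau_plus)  + spikes_E
  traces$y_minus <- d(traces$y_minus, params$tau_minus) + spikes_E
  traces$y_E     <- d(traces$y_E,     params$tau_yE)    + spikes_E
  traces$x_isp   <- d(traces$x_isp,   params$tau_STDP)  + spikes_I
  traces$y_isp   <- d(traces$y_isp,   params$tau_STDP)  + spikes_E
  traces
}

#' Apply the co-dependent excitatory rule for one step
#'
#' Event-driven evaluation of the excitatory learning rule on a dense
#' excitatory-to-excitatory weight matrix: at every postsynaptic spike the
#' synapse gains `A_LTP * x_plus_pre * E_post` and loses
#' `A_het * y_E_post * E_post^2`; at every presynaptic spike it loses
#' `A_LTD * y_minus_post * w`. All changes are multiplied by the inhibitory
#' gate of the postsynaptic neuron and weights are clipped at 0. Trace values
#' are read before this step's spike increments.
#'
#' @param w_EE Dense pre-by-post weight matrix (nS); `NA` entries denote
#'   absent synapses and are left untouched.
#' @param traces A [synaptic_traces()] (state before this step's increments).
#' @param spikes_E 0/1 excitatory spike indicators for this step.
#' @param currents A [current_traces()] object.
#' @param params A [plasticity_params()].
#' @return The updated weight matrix.
#' @export
apply_excitatory_plasticity <- function(w_EE, traces, spikes_E, currents,
                                        params = plasticity_params()) {
  n <- nrow(w_EE)
  stopifnot(ncol(w_EE) == n, length(spikes_E) == n)
  gate <- inhibitory_gate(currents$I_trace, params$I_star, params$gamma)
  E <- currents$E_trace
  dw <- matrix(0, n, n)
  cols <- which(spikes_E == 1L)   # postsynaptic spikes
  rows <- which(spikes_E == 1L)   # presynaptic spikes
  if (length(cols)) {
    # potentiation reads the presynaptic trace; in as-printed mode that trace
    # carries the postsynaptic neuron's spike history instead
    xp_term <- if (params$traces_as_printed) {
      matrix(rep(traces$x_plus[cols], each = n), nrow = n)
    } else {
      matrix(traces$x_plus, n, length(cols))
    }
    het <- params$A_het * traces$y_E[cols] * E[cols]^2 * gate[cols]
    dw[, cols] <- dw[, cols] +
      params$A_LTP * xp_term * matrix(rep(gate[cols] * E[cols], each = n), nrow = n) -
      matrix(rep(het, each = n), nrow = n)
  }
  if (length(rows)) {
    # depression reads the postsynaptic fast trace (presynaptic history when
    # as-printed), proportional to the current weight
    ym_term <- if (params$traces_as_printed) {
      matrix(rep(traces$y_minus[rows], times = n), nrow = length(rows))
    } else {
      matrix(rep(traces$y_minus, each = length(rows)), nrow = length(rows))
    }
    gate_m <- matrix(rep(gate, each = length(rows)), nrow = length(rows))
    dw[rows, ] <- dw[rows, ] -
      params$A_LTD * ym_term * gate_m * w_EE[rows, , drop = FALSE]
  }
  if (any(!is.finite(dw[!is.na(w_EE)])))
    stop("non-finite excitatory weight change (gate/trace/current instability)")
  out <- pmax(w_EE + dw, 0)
  out[is.na(w_EE)] <- NA
  out
}

#' Apply the co-dependent inhibitory rule for one step
#'
#' Event-driven evaluation of the inhibitory learning rule on a dense
#' inhibitory-to-excitatory weight matrix: every pre- or postsynaptic spike
#' changes the synapse by
#' `A_ISP * E_post * (E_post - alpha * I_post) * (x_isp_pre S_post + y_isp_post S_pre)`,
#' driving the postsynaptic excitatory/inhibitory current ratio toward
#' `alpha`. Weights are clipped at 0.
#'
#' @param w_IE Dense pre(I)-by-post(E) weight matrix (nS); `NA` entries denote
#'   absent synapses.
#' @param traces A [synaptic_traces()] (state before this step's increments).
#' @param currents A [current_traces()] for the postsynaptic E population.
#' @param spikes_E,spikes_I 0/1 spike indicators for this step.
#' @param params A [plasticity_params()].
#' @return The updated weight matrix.
#' @export
apply_inhibitory_plasticity <- function(w_IE, traces, currents,
                                        spikes_E, spikes_I,
                                        params = plasticity_params()) {
  n_I <- nrow(w_IE); n_E <- ncol(w_IE)
  stopifnot(length(spikes_I) == n_I, length(spikes_E) == n_E)
  E <- currents$E_trace
  I <- currents$I_trace
  drive <- params$A_ISP * E * (E - params$alpha * I)   # per postsynaptic neuron
  dw <- matrix(0, n_I, n_E)
  post_sp <- which(spikes_E == 1L)
  pre_sp  <- which(spikes_I == 1L)
  if (!params$traces_as_printed) {
    if (length(post_sp))
      dw[, post_sp] <- dw[, post_sp] + outer(traces$x_isp, drive[post_sp])
    if (length(pre_sp))
      dw[pre_sp, ] <- dw[pre_sp, ] +
        matrix(rep(traces$y_isp * drive, each = length(pre_sp)), nrow = length(pre_sp))
  } else {
    # printed form: the "presynaptic" trace carries postsynaptic spikes and
    # vice versa, so the read-out sides swap
    if (length(post_sp))
      dw[, post_sp] <- dw[, post_sp] +
        matrix(rep(traces$y_isp[post_sp] * drive[post_sp], each = n_I), nrow = n_I)
    if (length(pre_sp))
      dw[pre_sp, ] <- dw[pre_sp, ] + outer(traces$x_isp[pre_sp], drive)
  }
  if (any(!is.finite(dw[!is.na(w_IE)])))
    stop("non-finite inhibitory weight change (trace/current instability)")
  out <- pmax(w_IE + dw, 0)
  out[is.na(w_IE)] <- NA
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
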