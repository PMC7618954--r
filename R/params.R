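#' Neuron model parameters
#'
#' Parameters of the conductance-based leaky integrate-and-fire neuron with an
#' after-hyperpolarisation (AHP) channel. The membrane potential obeys
#' \deqn{\tau_m dV/dt = (V_{rest} - V) + \sum_X g_X (V_X - V)}
#' over channels X in AHP, AMPA, GABA, NMDA, with conductances treated as
#' dimensionless multiples of the leak conductance (their numerical values are
#' quoted in nS). A neuron fires when V crosses `V_th` from below, is reset to
#' `V_rest`, and is clamped there for the refractory period of its class.
#'
#' @param tau_m Membrane time constant (ms).
#' @param V_rest Resting potential (mV); also the post-spike reset value.
#' @param V_th Firing threshold (mV).
#' @param V_AMPA,V_NMDA Excitatory reversal potentials (mV).
#' @param V_GABA,V_AHP Inhibitory / AHP reversal potentials (mV).
#' @param tau_ref_E,tau_ref_I Refractory periods of excitatory and inhibitory
#'   neurons (ms).
#' @param tau_AHP Decay time of the AHP conductance (ms).
#' @param A_AHP AHP conductance increment per postsynaptic spike (nS).
#' @param tau_AMPA,tau_GABA,tau_NMDA Synaptic conductance decay times (ms).
#' @param g_L Leak conductance (nS) normalising the synaptic and AHP
#'   conductances in the membrane equation (the dimensionless conductance of
#'   channel X is `g_X / g_L`); sets the network's operating point, chosen so
#'   the bare network sits in a low-rate balanced state.
#' @param ahp_inhibitory Apply the AHP (spike-frequency adaptation) to
#'   inhibitory neurons too? Default `FALSE`: adaptation acts on excitatory
#'   cells while the interneurons are fast-spiking and non-adapting, the
#'   convention of this model family, and necessary for inhibitory firing to
#'   track network excitation steeply enough to control it.
#' @param nmda_mode `"spike"` (default): every excitatory spike increments
#'   the NMDA conductance by `nmda_fraction * w` (and AMPA by `w`);
#'   `"filtered"`: the NMDA conductance instead relaxes toward the AMPA
#'   conductance with time constant `tau_NMDA`.
#' @param nmda_fraction Weight fraction entering the NMDA channel in spike
#'   mode (the NMDA/AMPA amplitude ratio every simulator in this model
#'   family exposes). 1 reproduces the synapse equation literally, but then
#'   the slow channel carries ~30x the fast channel's charge and the
#'   recurrent network saturates at the printed weights; the default keeps
#'   the excitatory recurrence just subcritical so that inhibition and
#'   adaptation control it.
#'
#' @return A list of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params()
#' p$tau_m
neuron_params <- function(tau_m = 30, V_rest = -65, V_th = -50,
                          V_AMPA = 0, V_NMDA = 0, V_GABA = -80, V_AHP = -80,
                          tau_ref_E = 5, tau_ref_I = 2.5,
                          tau_AHP = 100, A_AHP = 5,
                          tau_AMPA = 5, tau_GABA = 10, tau_NMDA = 150,
                          g_L = 1.2, nmda_mode = c("spike", "filtered"),
                          nmda_fraction = 0.16, ahp_inhibitory = FALSE) {
  nmda_mode <- match.arg(nmda_mode)
  if (nmda_fraction < 0) stop("nmda_fraction must be >= 0")
  p <- list(
    tau_m = tau_m, V_rest = V_rest, V_th = V_th,
    V_AMPA = V_AMPA, V_NMDA = V_NMDA, V_GABA = V_GABA, V_AHP = V_AHP,
    tau_ref_E = tau_ref_E, tau_ref_I = tau_ref_I,
    tau_AHP = tau_AHP, A_AHP = A_AHP,
    tau_AMPA = tau_AMPA, tau_GABA = tau_GABA, tau_NMDA = tau_NMDA,
    g_L = g_L, nmda_mode = nmda_mode, nmda_fraction = nmda_fraction,
    ahp_inhibitory = isTRUE(ahp_inhibitory)
  )
  if (g_L <= 0) stop("g_L must be > 0")
  taus <- c(p$tau_m, p$tau_ref_E, p$tau_ref_I, p$tau_AHP,
            p$tau_AMPA, p$tau_GABA, p$tau_NMDA)
  num <- unlist(p[vapply(p, is.numeric, logical(1))])
  if (any(!is.finite(num))) stop("neuron parameters must be finite")
  if (any(taus <= 0)) stop("all time constants must be > 0")
  if (!(p$V_rest < p$V_th)) stop("V_rest must be below V_th")
  if (!(p$V_GABA <= p$V_rest && p$V_th < p$V_AMPA))
    stop("reversal potentials must satisfy V_GABA <= V_rest < V_th < V_AMPA")
  structure(p, class = "neuron_params")
}

#' Co-dependent plasticity parameters
#'
#' Parameters of the co-dependent excitatory and inhibitory learning rules.
#' Excitatory (E-to-E) weight changes combine spike-timing terms with the
#' postsynaptic neuron's filtered NMDA current trace E and are multiplicatively
#' gated by `exp(-(I/I_star)^gamma)`, where I is the filtered GABA current
#' trace. Inhibitory (I-to-E) weights change as
#' `A_ISP * E * (E - alpha * I) * (x_pre S_post + y_post S_pre)`, which has its
#' fixed point at the excitatory/inhibitory balance `E = alpha * I`.
#'
#' `current_scale_E` / `current_scale_I` convert the model's conductance-times-
#' driving-force currents into the unitless trace scale on which `I_star` and
#' `alpha` are defined; see [calibrate_currents()].
#'
#' @param A_LTP,A_LTD,A_het Excitatory learning rates (potentiation, depression,
#'   heterosynaptic).
#' @param I_star Gate level: the inhibitory trace value at which the gate
#'   equals exp(-1).
#' @param gamma Gate shape exponent (>= 1).
#' @param tau_plus,tau_minus,tau_yE Decay times (ms) of the pre-spike trace,
#'   the fast post-spike trace and the slow post-spike trace used by the
#'   heterosynaptic term.
#' @param A_ISP Inhibitory learning rate.
#' @param alpha Excitatory/inhibitory balance point in trace units.
#' @param tau_STDP Decay time (ms) of the symmetric inhibitory-rule traces.
#' @param tau_E_curr,tau_I_curr Decay times (ms) of the filtered NMDA and GABA
#'   current traces.
#' @param current_scale_E,current_scale_I Multiplicative calibration of the two
#'   current traces (see [calibrate_currents()]).
#' @param traces_as_printed If `TRUE`, the pre/post drive terms of the spike
#'   traces are swapped (each trace is read from the other side of the
#'   synapse); the default follows the textual description in which
#'   presynaptic traces are driven by presynaptic spikes.
#'
#' @return A list of class `plasticity_params`.
#' @export
plasticity_params <- function(A_LTP = 3e-4, A_LTD = 3e-5, A_het = 1.5e-8,
                              I_star = 200, gamma = 3,
                              tau_plus = 16.8, tau_minus = 33.7, tau_yE = 100,
                              A_ISP = 1e-3, alpha = 1, tau_STDP = 20,
                              tau_E_curr = 10, tau_I_curr = 100,
                              current_scale_E = 1, current_scale_I = 1,
                              traces_as_printed = FALSE) {
  p <- list(
    A_LTP = A_LTP, A_LTD = A_LTD, A_het = A_het,
    I_star = I_star, gamma = gamma,
    tau_plus = tau_plus, tau_minus = tau_minus, tau_yE = tau_yE,
    A_ISP = A_ISP, alpha = alpha, tau_STDP = tau_STDP,
    tau_E_curr = tau_E_curr, tau_I_curr = tau_I_curr,
    current_scale_E = current_scale_E, current_scale_I = current_scale_I,
    traces_as_printed = isTRUE(traces_as_printed)
  )
  if (any(c(p$A_LTP, p$A_LTD, p$A_het, p$A_ISP) < 0))
    stop("learning rates must be >= 0")
  if (any(c(p$tau_plus, p$tau_minus, p$tau_yE, p$tau_STDP,
            p$tau_E_curr, p$tau_I_curr) <= 0))
    stop("all time constants must be > 0")
  if (p$gamma < 1) stop("gamma must be >= 1")
  if (p$alpha <= 0) stop("alpha must be > 0")
  if (p$I_star <= 0) stop("I_star must be > 0")
  structure(p, class = "plasticity_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> conductance-based LIF with AHP\n")
  cat(sprintf("  tau_m %g ms, V_rest %g mV, V_th %g mV, refractory E/I %g/%g ms\n",
              x$tau_m, x$V_rest, x$V_th, x$tau_ref_E, x$tau_ref_I))
  cat(sprintf("  tau AMPA/GABA/NMDA/AHP %g/%g/%g/%g ms, A_AHP %g nS\n",
              x$tau_AMPA, x$tau_GABA, x$tau_NMDA, x$tau_AHP, x$A_AHP))
  invisible(x)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params> co-dependent excitatory + inhibitory rules\n")
  cat(sprintf("  A_LTP %g, A_LTD %g, A_het %g, gate I* = %g (gamma %g)\n",
              x$A_LTP, x$A_LTD, x$A_het, x$I_star, x$gamma))
  cat(sprintf("  A_ISP %g, alpha %g, tau_STDP %g ms\n",
              x$A_ISP, x$alpha, x$tau_STDP))
  invisible(x)
}
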