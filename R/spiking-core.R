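#' Create a population state
#'
#' Per-neuron dynamical state of a population of conductance-based LIF
#' neurons: membrane potential, the four conductances and the remaining
#' refractory time. Conductances are dimensionless multiples of the leak
#' conductance (values quoted in nS).
#'
#' @param n Number of neurons.
#' @param params A [neuron_params()] object.
#' @param V Initial membrane potentials (recycled to length `n`).
#'
#' @return A list of class `population_state` with numeric vectors `V`,
#'   `g_AHP`, `g_AMPA`, `g_GABA`, `g_NMDA` and `refractory_remaining`.
#' @export
population_state <- function(n, params = neuron_params(), V = params$V_rest) {
  stopifnot(n >= 1)
  structure(list(
    V = rep_len(V, n),
    g_AHP = numeric(n), g_AMPA = numeric(n),
    g_GABA = numeric(n), g_NMDA = numeric(n),
    refractory_remaining = numeric(n)
  ), class = "population_state")
}

#' One forward-Euler membrane step
#'
#' Advances the membrane potential of every neuron by one step of width `dt`
#' using forward Euler on
#' \deqn{\tau_m dV/dt = (V_{rest}-V) + g_{AHP}(V_{AHP}-V) + g_{AMPA}(V_{AMPA}-V)
#'   + g_{GABA}(V_{GABA}-V) + g_{NMDA}(V_{NMDA}-V).}
#' Neurons still refractory are held clamped at `V_rest` and their remaining
#' refractory time is decremented. Neurons whose updated potential reaches
#' `V_th` emit a spike, are reset to `V_rest` and clamped for the refractory
#' period of their class.
#'
#' @param state A [population_state()].
#' @param params A [neuron_params()].
#' @param dt Step width (ms).
#' @param class_E Logical vector: `TRUE` for excitatory neurons (refractory
#'   `tau_ref_E`), `FALSE` for inhibitory (`tau_ref_I`). Scalar recycled.
#'
#' @return A list with the updated `state` and `spikes`, a 0/1 integer vector.
#' @export
#' @examples
#' st <- population_state(3)
#' out <- integrate_membrane(st, neuron_params(), dt = 0.1)
#' out$spikes
integrate_membrane <- function(state, params = neuron_params(), dt = 0.1,
                               class_E = TRUE) {
  stopifnot(dt > 0)
  n <- length(state$V)
  class_E <- rep_len(class_E, n)
  if (any(state$g_AHP < 0 | state$g_AMPA < 0 | state$g_GABA < 0 | state$g_NMDA < 0))
    stop("conductances must be non-negative")
  refr <- state$refractory_remaining > 0
  p <- params
  drive <- (p$V_rest - state$V) +
    (state$g_AHP * (p$V_AHP - state$V) +
       state$g_AMPA * (p$V_AMPA - state$V) +
       state$g_GABA * (p$V_GABA - state$V) +
       state$g_NMDA * (p$V_NMDA - state$V)) / p$g_L
  V_new <- state$V + dt / p$tau_m * drive
  V_new <- pmin(pmax(V_new, p$V_GABA), p$V_AMPA)  # reversal potentials bound V
  V_new[refr] <- p$V_rest
  if (any(!is.finite(V_new))) {
    bad <- which(!is.finite(V_new))[1]
    stop(sprintf("numerical instability: non-finite membrane potential at neuron %d", bad))
  }
  spikes <- as.integer(!refr & V_new >= p$V_th)
  fired <- spikes == 1L
  V_new[fired] <- p$V_rest
  rr <- pmax(state$refractory_remaining - dt, 0)
  rr[fired] <- ifelse(class_E[fired], p$tau_ref_E, p$tau_ref_I)
  state$V <- V_new
  state$refractory_remaining <- rr
  list(state = state, spikes = spikes)
}

#' Update the after-hyperpolarisation conductance
#'
#' Euler decay of `g_AHP` with time constant `tau_AHP`, plus an increment of
#' `A_AHP` for every postsynaptic spike emitted this step.
#'
#' @inheritParams integrate_membrane
#' @param spikes 0/1 spike indicators from the same step.
#' @return The updated state.
#' @export
update_ahp <- function(state, spikes, params = neuron_params(), dt = 0.1) {
  stopifnot(length(spikes) == length(state$g_AHP))
  g <- state$g_AHP * (1 - dt / params$tau_AHP) + params$A_AHP * spikes
  if (any(g < 0)) stop("negative AHP conductance (invariant violation)")
  state$g_AHP <- g
  state
}

#' Update a synaptic conductance channel
#'
#' Euler decay of a conductance vector with time constant `tau_X`, plus
#' increments `w[j, i]` for every presynaptic spike of neuron `j` onto target
#' `i`. `weights` may be a dense matrix (presynaptic neurons in rows) or a
#' vector when there is a single target.
#'
#' @param g Per-target conductance vector (nS).
#' @param tau_X Channel decay time (ms).
#' @param presyn_spikes 0/1 indicators of presynaptic spikes this step.
#' @param weights Presynaptic-by-target weight matrix (nS), non-negative.
#' @param dt Step width (ms).
#' @return The updated conductance vector.
#' @export
#' @examples
#' update_conductance(0, 5, presyn_spikes = 1, weights = 0.25, dt = 0.1)
update_conductance <- function(g, tau_X, presyn_spikes, weights, dt = 0.1) {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(presyn_spikes))
    stop("weights rows must match the presynaptic spike vector")
  if (ncol(weights) != length(g))
    stop("weights columns must match the conductance vector")
  if (any(weights < 0)) stop("weights must be non-negative")
  g * (1 - dt / tau_X) + drop(crossprod(weights, presyn_spikes))
}

#' Poisson spike generation
#'
#' Independent Bernoulli(rate * dt) spikes per neuron and time step, the
#' discrete-time realisation of homogeneous Poisson spike trains.
#' Reproducible under [set.seed()].
#'
#' @param rate Firing rate (Hz).
#' @param n_neurons Number of independent Poisson neurons.
#' @param duration Length of the generated segment (s).
#' @param dt Step width (ms).
#' @return An integer matrix of 0/1 indicators, steps in rows, neurons in
#'   columns.
#' @export
#' @examples
#' set.seed(1)
#' sum(poisson_spikes(10, 5, duration = 1))
poisson_spikes <- function(rate, n_neurons, duration, dt = 0.1) {
  stopifnot(rate >= 0, n_neurons >= 1, duration > 0, dt > 0)
  p <- rate * dt / 1000
  if (p >= 1) stop("rate * dt must be < 1 (one spike per bin at most)")
  n_steps <- round(duration * 1000 / dt)
  matrix(as.integer(stats::runif(n_steps * n_neurons) < p),
         nrow = n_steps, ncol = n_neurons)
}

#' Write a spike raster as tab-separated text
#'
#' Two columns, `time_s` and `neuron_id` (0-based), populations offset in the
#' order excitatory, inhibitory, input groups.
#'
#' @param spikes A data frame with columns `time_s` and `neuron_id`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(spikes, path) {
  stopifnot(all(c("time_s", "neuron_id") %in% names(spikes)))
  utils::write.table(spikes[, c("time_s", "neuron_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
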