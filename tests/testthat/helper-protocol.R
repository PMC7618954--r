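# Fabricate a protocol_result with Poisson spikes at prescribed per-assembly
# rates, for testing the analysis operations independently of the simulator.
fake_result <- function(rate_base = rep(2, 6), rate_stim = rep(2, 6),
                        n_per = 20, n_asm = 6, probe_id = 1,
                        Tb = 2, Ts = 3.3, seed = 1,
                        dw = NULL) {
  set.seed(seed)
  n_E <- n_per * n_asm + 40
  members <- lapply(seq_len(n_asm), function(k) (k - 1) * n_per + 0:(n_per - 1))
  gen_window <- function(rates, t0, t1) {
    out <- list(tibble::tibble(time_s = numeric(0), neuron_id = numeric(0)))
    for (k in seq_len(n_asm)) {
      for (m in members[[k]]) {
        nsp <- stats::rpois(1, rates[k] * (t1 - t0))
        if (nsp > 0)
          out[[length(out) + 1]] <- tibble::tibble(
            time_s = sort(stats::runif(nsp, t0, t1)), neuron_id = m)
      }
    }
    dplyr::bind_rows(out)
  }
  sp_b <- gen_window(rate_base, 0, Tb)
  sp_s <- gen_window(rate_stim, Tb, Tb + Ts)
  spikes <- dplyr::bind_rows(
    dplyr::mutate(sp_b, stage = "baseline"),
    dplyr::mutate(sp_s, stage = "stimulus"))
  # a toy E-E pattern: one synapse between every ordered assembly pair
  pairs <- expand.grid(a = seq_len(n_asm), b = seq_len(n_asm))
  pairs <- pairs[pairs$a != pairs$b, ]
  ee_pre <- vapply(pairs$a, function(a) members[[a]][1], numeric(1))
  ee_post <- vapply(pairs$b, function(b) members[[b]][2], numeric(1))
  w_before <- rep(0.25, nrow(pairs))
  w_after <- w_before
  if (!is.null(dw)) {
    for (i in seq_len(nrow(pairs)))
      w_after[i] <- w_before[i] + dw[pairs$a[i], pairs$b[i]]
  }
  structure(list(
    spikes = spikes,
    windows = list(baseline = c(0, Tb), stimulus = c(Tb, Tb + Ts)),
    snapshots = list(before = list(ee = w_before), after = list(ee = w_after)),
    ee_pre = ee_pre, ee_post = ee_post,
    members = list(E = members), n_E = n_E, n_I = 10,
    probe_id = probe_id, condition = "synthetic",
    layout = NULL), class = "protocol_result")
}
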