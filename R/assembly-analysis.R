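#' Ring distance between assemblies
#'
#' @param a,b Assembly ids (1-based, vectorised).
#' @param n Number of assemblies on the ring.
#' @return Integer distance(s).
#' @export
ring_distance <- function(a, b, n = 6) {
  d <- abs(a - b)
  pmin(d, n - d)
}

window_of <- function(result, window) {
  if (is.character(window)) {
    window <- match.arg(window, c("stimulus", "baseline"))
    return(result$windows[[window]])
  }
  stopifnot(is.numeric(window), length(window) == 2)
  window
}

per_neuron_rates <- function(result, window) {
  w <- window_of(result, window)
  if (diff(w) <= 0) stop("empty analysis window")
  sp <- result$spikes
  sel <- sp$time_s > w[1] & sp$time_s <= w[2] & sp$neuron_id < result$n_E
  counts <- tabulate(sp$neuron_id[sel] + 1L, nbins = result$n_E)
  counts / diff(w)
}

#' Per-assembly mean firing rates
#'
#' Mean spike count per excitatory member neuron per second within a window
#' of a probe recording. Neurons shared between overlapping assemblies count
#' in every assembly containing them.
#'
#' @param result A `protocol_result` from [probe_assembly()].
#' @param window `"stimulus"`, `"baseline"`, or a numeric `c(from, to)` in
#'   seconds.
#' @return A tibble: `assembly`, `distance` (ring distance from the probed
#'   assembly), `rate_hz`.
#' @export
assembly_rates <- function(result, window = "stimulus") {
  r <- per_neuron_rates(result, window)
  EM <- result$members$E
  n_asm <- length(EM)
  tibble::tibble(
    assembly = seq_len(n_asm),
    distance = ring_distance(seq_len(n_asm), result$probe_id, n_asm),
    rate_hz = vapply(EM, function(m) mean(r[m + 1L]), numeric(1)))
}

#' Mean synaptic weight change between assemblies
#'
#' Entry (a, b) is the mean over existing excitatory synapses from assembly
#' a to assembly b of the weight change across the probe (after minus
#' before). Identically zero when plasticity is frozen.
#'
#' @param result A `protocol_result`.
#' @param before,after Optional weight vectors over the E-E synapses
#'   (default: the probe's snapshots). Must share the recording's sparsity
#'   pattern.
#' @return A base matrix (assemblies x assemblies) of mean weight changes
#'   (nS).
#' @export
weight_change_matrix <- function(result, before = NULL, after = NULL) {
  before <- before %||% result$snapshots$before$ee
  after <- after %||% result$snapshots$after$ee
  if (length(before) != length(result$ee_pre) ||
      length(after) != length(result$ee_pre))
    stop("weight snapshots do not match the network's E-E sparsity pattern")
  EM <- result$members$E
  n_asm <- length(EM)
  dw <- after - before
  out <- matrix(NA_real_, n_asm, n_asm,
                dimnames = list(paste0("from_", seq_len(n_asm)),
                                paste0("to_", seq_len(n_asm))))
  for (a in seq_len(n_asm)) {
    pre_in <- result$ee_pre %in% EM[[a]]
    for (b in seq_len(n_asm)) {
      idx <- pre_in & result$ee_post %in% EM[[b]]
      out[a, b] <- if (any(idx)) mean(dw[idx]) else 0
    }
  }
  out
}

#' Functional overlap with the probe-activated ensemble
#'
#' The percentage of each assembly's excitatory neurons recruited by the
#' probe: neurons whose stimulus-window firing rate exceeds their baseline
#' rate by more than `k` standard deviations of the rate estimator
#' (Poisson counting noise over the two windows), i.e. a per-neuron rate
#' elevation z-test at threshold `k`. Near-silent baselines are floored at
#' one expected spike per baseline window so single stray spikes do not
#' count as recruitment. The structural variant instead counts neurons
#' whose summed incoming weight from the probed assembly increased over the
#' probe.
#'
#' @param result A `protocol_result`.
#' @param k Threshold in SDs of the rate estimator (the threshold rule).
#' @param metric `"functional"` (rate threshold) or `"structural"`
#'   (strengthened incoming weights).
#' @return A tibble: `assembly`, `distance`, `overlap_pct`.
#' @export
functional_overlap <- function(result, k = 2,
                               metric = c("functional", "structural")) {
  metric <- match.arg(metric)
  EM <- result$members$E
  n_asm <- length(EM)
  if (metric == "functional") {
    Tb <- diff(result$windows$baseline)
    Ts <- diff(result$windows$stimulus)
    base_rate <- per_neuron_rates(result, "baseline")
    stim_rate <- per_neuron_rates(result, "stimulus")
    r0 <- pmax(base_rate, 1 / Tb)
    se <- sqrt(r0 / Ts + r0 / Tb)
    recruited <- function(members) {
      m <- members + 1L
      if (all(base_rate[m] == 0) && all(stim_rate[m] == 0))
        stop("degenerate baseline: assembly silent in both windows")
      100 * mean(stim_rate[m] > base_rate[m] + k * se[m])
    }
  } else {
    dw_in <- rep(0, result$n_E)
    idx <- result$ee_pre %in% EM[[result$probe_id]]
    d <- result$snapshots$after$ee[idx] - result$snapshots$before$ee[idx]
    agg <- tapply(d, result$ee_post[idx], sum)
    dw_in[as.integer(names(agg)) + 1L] <- agg
    recruited <- function(members) 100 * mean(dw_in[members + 1L] > 0)
  }
  tibble::tibble(
    assembly = seq_len(n_asm),
    distance = ring_distance(seq_len(n_asm), result$probe_id, n_asm),
    overlap_pct = vapply(EM, recruited, numeric(1)))
}

#' Assembly-level summary of a probe
#'
#' Per-assembly stimulus and baseline rates, ring distance from the probed
#' assembly, functional overlap, and the mean weight change from the probed
#' assembly.
#'
#' @param result A `protocol_result`.
#' @param k Overlap threshold rule (baseline SDs).
#' @return A tibble of class `assembly_summary`.
#' @export
assembly_summary <- function(result, k = 2) {
  rs <- assembly_rates(result, "stimulus")
  rb <- assembly_rates(result, "baseline")
  ov <- functional_overlap(result, k = k)
  dw <- weight_change_matrix(result)
  n_asm <- nrow(rs)
  out <- tibble::tibble(
    assembly = rs$assembly, distance = rs$distance,
    rate_stim = rs$rate_hz, rate_base = rb$rate_hz,
    overlap_pct = ov$overlap_pct,
    dw_from_probe = dw[result$probe_id, ])
  class(out) <- c("assembly_summary", class(out))
  attr(out, "probe_id") <- result$probe_id
  attr(out, "condition") <- result$condition
  out
}

#' Distance gradient of the spread of association
#'
#' Averages stimulus-window rates over symmetric ring distances from the
#' probed assembly (on a 6-ring: d = 1 averages assemblies 2 and 6, d = 2
#' averages 3 and 5, d = 3 is assembly 4), and reports the Spearman rank
#' correlation between distance and rate together with a strict-gradient
#' flag `rate(d=1) > rate(d=2) > rate(d=3)`. A clear spread of association
#' yields correlation -1 and a `TRUE` flag; a selective (non-spreading)
#' network yields no systematic ordering.
#'
#' @param summary An [assembly_summary()] (or any tibble with `distance` and
#'   a rate column).
#' @param value Column to grade (default `rate_stim`).
#' @return A list of class `spread_gradient`: `by_distance` tibble,
#'   `correlation`, `strict`.
#' @export
spread_gradient <- function(summary, value = "rate_stim") {
  if (!all(c("distance", value) %in% names(summary)))
    stop("summary must contain columns 'distance' and '", value, "'")
  nonself <- summary[summary$distance > 0, ]
  if (!nrow(nonself)) stop("summary contains no non-probed assemblies")
  by_d <- nonself |>
    dplyr::group_by(distance = .data$distance) |>
    dplyr::summarise(value = mean(.data[[value]]), .groups = "drop") |>
    dplyr::arrange(.data$distance)
  rho <- if (stats::sd(by_d$value) == 0) 0 else
    stats::cor(by_d$distance, by_d$value, method = "spearman")
  strict <- all(diff(by_d$value) < 0)
  structure(list(by_distance = by_d, correlation = rho, strict = strict),
            class = "spread_gradient")
}

#' @export
print.spread_gradient <- function(x, ...) {
  cat("<spread_gradient>\n")
  print(x$by_distance)
  cat(sprintf("  rank correlation (distance vs value): %.3f; strict gradient: %s\n",
              x$correlation, x$strict))
  invisible(x)
}

#' Binned per-assembly rate time series of a probe recording
#'
#' @param x A `protocol_result`.
#' @param bin_s Bin width (s).
#' @param ... Unused.
#' @return A tibble: `assembly`, `time_s` (bin centre), `rate_hz`, `stage`.
#' @export
tidy.protocol_result <- function(x, bin_s = 0.1, ...) {
  t0 <- x$windows$baseline[1]; t1 <- x$windows$stimulus[2]
  breaks <- seq(t0, t1, by = bin_s)
  if (max(breaks) < t1) breaks <- c(breaks, t1)   # cover a partial last bin
  EM <- x$members$E
  sp <- x$spikes[x$spikes$neuron_id < x$n_E, ]
  purrr::map_dfr(seq_along(EM), function(a) {
    m <- EM[[a]]
    tt <- sp$time_s[sp$neuron_id %in% m]
    h <- graphics::hist(tt, breaks = breaks, plot = FALSE)
    tibble::tibble(
      assembly = a,
      time_s = h$mids,
      rate_hz = h$counts / (length(m) * bin_s),
      stage = ifelse(h$mids > x$windows$stimulus[1], "stimulus", "baseline"))
  })
}

#' @export
glance.protocol_result <- function(x, ...) {
  g <- spread_gradient(assembly_summary(x))
  tibble::tibble(condition = x$condition, probe = x$probe_id,
                 rate_probe = assembly_rates(x, "stimulus")$rate_hz[x$probe_id],
                 gradient_cor = g$correlation, strict_gradient = g$strict)
}

#' Plot a probe recording as per-assembly rate traces
#'
#' @param object A `protocol_result`.
#' @param bin_s Bin width (s).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.protocol_result <- function(object, bin_s = 0.1, ...) {
  d <- tidy(object, bin_s = bin_s)
  stim <- object$windows$stimulus
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$rate_hz,
                                  colour = factor(.data$assembly))) +
    ggplot2::annotate("rect", xmin = stim[1], xmax = stim[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "assembly rate (Hz)",
                  colour = "assembly",
                  title = sprintf("Probe of assembly %d (%s)",
                                  object$probe_id, object$condition)) +
    ggplot2::theme_minimal()
}

#' Write an assembly summary and weight-change table
#'
#' Emits the tidy per-assembly summary as CSV alongside the full
#' assembly-by-assembly mean weight-change table.
#'
#' @param result A `protocol_result`.
#' @param path Output CSV path for the summary; the weight table goes to
#'   `<path>_dw.csv`.
#' @return `path`, invisibly.
#' @export
write_assembly_summary <- function(result, path) {
  s <- assembly_summary(result)
  utils::write.csv(s, path, row.names = FALSE)
  dw <- weight_change_matrix(result)
  utils::write.csv(dw, sub("\\.csv$", "_dw.csv", path))
  invisible(path)
}
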