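#' Preprocess a pupil recording
#'
#' Linearly interpolates the pupil trace across blink/missing periods (from
#' the recording's `missing` mask) and smooths with a Gaussian kernel. The
#' kernel width is an SD of `kernel_ms` by default; `kernel_mode = "fwhm"`
#' interprets `kernel_ms` as full width at half maximum instead. The kernel
#' is renormalised at the edges so a constant trace passes through
#' unchanged.
#'
#' @param rec A data frame with columns `time_s`, `pupil`, `missing` (0/1),
#'   and optionally `event` ("", "regular", "oddball") and `block`.
#' @param kernel_ms Gaussian kernel width (ms).
#' @param kernel_mode `"sd"` or `"fwhm"`.
#' @return The recording with `pupil` replaced by the cleaned, smoothed
#'   trace.
#' @export
pupil_preprocess <- function(rec, kernel_ms = 120, kernel_mode = c("sd", "fwhm")) {
  kernel_mode <- match.arg(kernel_mode)
  stopifnot(all(c("time_s", "pupil", "missing") %in% names(rec)))
  if (is.unsorted(rec$time_s, strictly = TRUE))
    stop("sample times must be strictly increasing")
  miss <- rec$missing > 0 | !is.finite(rec$pupil)
  if (mean(miss) > 0.5)
    stop("unusable recording: more than 50% of samples missing")
  x <- rec$pupil
  x[miss] <- NA
  if (any(miss)) {
    x <- stats::approx(rec$time_s[!miss], x[!miss], xout = rec$time_s,
                       rule = 2)$y
  }
  fs <- 1 / stats::median(diff(rec$time_s))
  sd_ms <- if (kernel_mode == "fwhm") kernel_ms / (2 * sqrt(2 * log(2)))
           else kernel_ms
  sd_samp <- sd_ms / 1000 * fs
  half <- max(1L, ceiling(4 * sd_samp))
  k <- stats::dnorm(seq(-half, half), sd = sd_samp)
  sm <- stats::filter(x, k / sum(k), sides = 2)
  # renormalise at the edges where the kernel is truncated
  ones <- stats::filter(rep(1, length(x)), k / sum(k), sides = 2)
  sm <- as.numeric(sm / ones)
  nas <- is.na(sm)
  sm[nas] <- x[nas]
  rec$pupil <- sm
  rec
}

#' Epoch a preprocessed recording with quality control
#'
#' Normalises pupil size per block as the percentage difference from the
#' block mean, cuts an epoch around every event onset, drops trials in which
#' the pupil signal was lost (interpolated) for more than `max_lost_ms`
#' within the epoch, flags the subject excluded when more than half the
#' trials are dropped, and baseline-corrects every epoch by subtracting its
#' mean over the `baseline_ms` pre-stimulus window.
#'
#' @param rec A preprocessed recording with an `event` column marking onset
#'   samples (`"regular"` / `"oddball"`) and a `block` column.
#' @param window Epoch window around onset, `c(from, to)` in seconds.
#' @param max_lost_ms Maximum tolerated interpolated-missing time per trial.
#' @param baseline_ms Pre-stimulus baseline window length.
#' @return A list of class `epoch_set`: `data` (retained trials x time),
#'   `times`, `condition`, `n_trials`, `n_dropped`, `excluded`.
#' @export
epoch_and_qc <- function(rec, window = c(-0.25, 10), max_lost_ms = 1000,
                         baseline_ms = 250) {
  stopifnot(all(c("time_s", "pupil", "missing", "event") %in% names(rec)))
  onsets <- which(rec$event %in% c("regular", "oddball"))
  if (!length(onsets)) stop("no events in recording")
  if (!"block" %in% names(rec)) rec$block <- 1L
  fs <- 1 / stats::median(diff(rec$time_s))
  norm <- stats::ave(rec$pupil, rec$block,
                     FUN = function(v) 100 * (v - mean(v)) / mean(v))
  i0 <- round(window[1] * fs); i1 <- round(window[2] * fs)
  idx_rel <- i0:i1
  times <- idx_rel / fs
  keep_on <- onsets[onsets + i0 >= 1 & onsets + i1 <= nrow(rec)]
  if (!length(keep_on)) stop("no events with a complete epoch window")
  epochs <- t(vapply(keep_on, function(o) norm[o + idx_rel],
                     numeric(length(idx_rel))))
  lost_ms <- vapply(keep_on, function(o)
    sum(rec$missing[o + idx_rel] > 0) / fs * 1000, numeric(1))
  cond <- rec$event[keep_on]
  drop <- lost_ms > max_lost_ms
  excluded <- mean(drop) > 0.5
  epochs <- epochs[!drop, , drop = FALSE]
  cond <- cond[!drop]
  bsel <- times >= -baseline_ms / 1000 & times < 0
  if (!any(bsel)) stop("epoch window does not cover the baseline period")
  if (nrow(epochs))
    epochs <- epochs - rowMeans(epochs[, bsel, drop = FALSE])
  structure(list(data = epochs, times = times, condition = cond,
                 n_trials = length(keep_on), n_dropped = sum(drop),
                 excluded = excluded, window = window,
                 baseline_ms = baseline_ms),
            class = "epoch_set")
}

#' Oddball-minus-regular pupil contrast
#'
#' The subject's mean epoched response to oddball stimuli minus the mean
#' response to regular stimuli.
#'
#' @param epochs An [epoch_and_qc()] result.
#' @return A numeric time course over `epochs$times`.
#' @export
oddball_contrast <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  no <- sum(epochs$condition == "oddball")
  nr <- sum(epochs$condition == "regular")
  if (no == 0 || nr == 0)
    stop("contrast undefined: a condition has no retained trials")
  colMeans(epochs$data[epochs$condition == "oddball", , drop = FALSE]) -
    colMeans(epochs$data[epochs$condition == "regular", , drop = FALSE])
}

# maximum cluster mass of one row of thresholded |t| values
max_cluster_mass <- function(tv, crit) {
  supra <- abs(tv) > crit
  if (!any(supra)) return(0)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  max(vapply(which(r$values), function(k)
    sum(abs(tv[starts[k]:ends[k]])), numeric(1)))
}

#' Two-group cluster-based permutation test on time courses
#'
#' Welch t statistics across subjects at every timepoint, thresholded at the
#' two-sided `cluster_p` critical value; contiguous supra-threshold runs are
#' scored by cluster mass (sum of |t|), and the familywise-corrected p of
#' each observed cluster is its rank in the permutation null distribution of
#' the maximum cluster mass obtained by permuting subject group labels.
#'
#' @param group_a,group_b Subject-by-timepoint matrices on a common grid.
#' @param times Timepoints (s); defaults to column index.
#' @param n_perm Number of label permutations.
#' @param alpha Familywise significance level for reporting.
#' @param cluster_p Two-sided cluster-forming threshold.
#' @return A list of class `cluster_test`: `clusters` (tibble with
#'   `start_s`, `end_s`, `mass`, `p_corrected`, `significant`), `t` (observed
#'   statistic), `times`, `crit`, `null_max` (permutation distribution).
#' @export
cluster_permutation <- function(group_a, group_b, times = NULL,
                                n_perm = 10000, alpha = 0.05,
                                cluster_p = 0.05) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b))
    stop("groups must share the same time grid")
  na <- nrow(group_a); nb <- nrow(group_b)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  T_ <- ncol(group_a)
  times <- times %||% seq_len(T_)
  X <- rbind(group_a, group_b)
  X2 <- X^2
  n <- na + nb
  crit <- stats::qt(1 - cluster_p / 2, df = n - 2)

  welch_t <- function(selA) {
    A <- X[selA, , drop = FALSE]; B <- X[-selA, , drop = FALSE]
    mA <- colMeans(A); mB <- colMeans(B)
    vA <- (colSums(X2[selA, , drop = FALSE]) - na * mA^2) / (na - 1)
    vB <- (colSums(X2[-selA, , drop = FALSE]) - nb * mB^2) / (nb - 1)
    (mA - mB) / sqrt(pmax(vA, 0) / na + pmax(vB, 0) / nb)
  }
  t_obs <- welch_t(seq_len(na))
  t_obs[!is.finite(t_obs)] <- 0

  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    tv <- welch_t(sample.int(n, na))
    tv[!is.finite(tv)] <- 0
    null_max[i] <- max_cluster_mass(tv, crit)
  }

  supra <- abs(t_obs) > crit
  clusters <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                             mass = numeric(0), p_corrected = numeric(0),
                             significant = logical(0))
  if (any(supra)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ks <- which(r$values)
    mass <- vapply(ks, function(k) sum(abs(t_obs[starts[k]:ends[k]])),
                   numeric(1))
    p <- vapply(mass, function(m) (1 + sum(null_max >= m)) / (1 + n_perm),
                numeric(1))
    clusters <- tibble::tibble(
      start_s = times[starts[ks]], end_s = times[ends[ks]],
      mass = mass, p_corrected = p, significant = p < alpha)
  }
  structure(list(clusters = clusters, t = t_obs, times = times,
                 crit = crit, alpha = alpha, n_perm = n_perm,
                 null_max = null_max),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%d permutations, alpha %.2g)\n",
              x$n_perm, x$alpha))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant),
                 min_p = if (nrow(x$clusters)) min(x$clusters$p_corrected) else NA_real_)
}

#' Plot a cluster permutation test
#'
#' The pointwise group statistic with significant clusters shaded.
#'
#' @param object A `cluster_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_test <- function(object, ...) {
  d <- tibble::tibble(time_s = object$times, t = object$t)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$t)) +
    ggplot2::geom_hline(yintercept = c(-object$crit, object$crit),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "Welch t") +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$significant, ]
  if (nrow(sig))
    p <- p + ggplot2::annotate("rect", xmin = sig$start_s, xmax = sig$end_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "firebrick")
  p
}

#' Run the full pupil pipeline for a two-group cohort
#'
#' Preprocess, epoch, QC and contrast every subject's recording, drop
#' excluded subjects, and run the two-group cluster permutation test on the
#' oddball-minus-regular contrast curves.
#'
#' @param recordings A named list of per-subject recordings (data frames).
#' @param groups Character vector of group labels aligned with `recordings`.
#' @param window Epoch window (s).
#' @param n_perm Permutations for the cluster test.
#' @param ... Passed to [cluster_permutation()].
#' @return A list: `test` (a `cluster_test`), `contrasts` (subject x time
#'   matrix), `groups`, `excluded` (logical per subject).
#' @export
pupil_pipeline <- function(recordings, groups, window = c(-0.25, 10),
                           n_perm = 10000, ...) {
  stopifnot(length(recordings) == length(groups))
  res <- lapply(recordings, function(r)
    epoch_and_qc(pupil_preprocess(r), window = window))
  excluded <- vapply(res, function(e) e$excluded, logical(1))
  keep <- which(!excluded)
  if (length(keep) < 4) stop("too few subjects retained after QC")
  contrasts <- t(vapply(res[keep], oddball_contrast,
                        numeric(length(res[[keep[1]]]$times))))
  g <- groups[keep]
  gl <- unique(g)
  if (length(gl) != 2) stop("exactly two groups required")
  test <- cluster_permutation(contrasts[g == gl[1], , drop = FALSE],
                              contrasts[g == gl[2], , drop = FALSE],
                              times = res[[keep[1]]]$times,
                              n_perm = n_perm, ...)
  list(test = test, contrasts = contrasts, groups = g, excluded = excluded)
}
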