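#' Specification for synthetic behavioural choices
#'
#' Generates implicit-test style choice data on a ring task: each trial
#' probes one bird with a 6-cue option set (the correct context plus 5
#' contexts sampled uniformly without replacement). The subject answers
#' correctly with probability `p_correct`; otherwise an incorrect option is
#' drawn with probability proportional to `exp(-lambda * (d - 1))`, where
#' `d` is the link distance of the cue from the correct context. `lambda`
#' is the spread (decay-rate) parameter: 0 gives uniform errors (no
#' overgeneralisation), larger values concentrate errors on ring
#' neighbours.
#'
#' @param n_nodes Ring size.
#' @param n_subjects Subjects per group.
#' @param n_trials Trials per subject (default: one probe per bird).
#' @param p_correct Probability of a correct choice (default 0.25, the
#'   near-chance accuracy regime of the implicit test).
#' @param lambda_atx,lambda_plc Spread parameter per group (>= 0). The
#'   defaults give the placebo group uniform errors and the atomoxetine
#'   group an expected overgeneralisation score of about 10 percentage
#'   points (see [expected_og_errors()]).
#' @param n_options Option-set size.
#' @return A list of class `behaviour_gen_spec`.
#' @export
behaviour_gen_spec <- function(n_nodes = 11, n_subjects = 22, n_trials = 11,
                               p_correct = 0.25,
                               lambda_atx = 0.19, lambda_plc = 0,
                               n_options = 6) {
  stopifnot(p_correct >= 0, p_correct <= 1,
            lambda_atx >= 0, lambda_plc >= 0,
            n_options >= 2, n_options <= n_nodes)
  structure(list(n_nodes = n_nodes, n_subjects = n_subjects,
                 n_trials = n_trials, p_correct = p_correct,
                 lambda_atx = lambda_atx, lambda_plc = lambda_plc,
                 n_options = n_options),
            class = "behaviour_gen_spec")
}

sample_error_choice <- function(wrong, correct, n_nodes, lambda) {
  d <- link_distance(rep(correct, length(wrong)), wrong, n_nodes)
  w <- exp(-lambda * (d - 1))
  wrong[sample.int(length(wrong), 1, prob = w)]
}

#' Generate synthetic choice trials
#'
#' @param spec A [behaviour_gen_spec()].
#' @param task A [ring_task()] (defaults to the generator spec's ring size).
#' @param groups Group labels to generate (`lambda_atx` applies to `"ATX"`,
#'   `lambda_plc` to `"PLC"`).
#' @return A tibble of trials: `subject`, `group`, `probe_bird`, `options`
#'   (semicolon-joined context ids), `chosen`, `correct`. Reproducible under
#'   [set.seed()].
#' @export
#' @examples
#' set.seed(1)
#' gen_choices(behaviour_gen_spec(n_subjects = 2))
gen_choices <- function(spec = behaviour_gen_spec(), task = NULL,
                        groups = c("ATX", "PLC")) {
  task <- task %||% ring_task(spec$n_nodes)
  n <- task$n_nodes
  rows <- list()
  for (g in groups) {
    lam <- if (toupper(g) == "ATX") spec$lambda_atx else spec$lambda_plc
    for (s in seq_len(spec$n_subjects)) {
      sid <- paste0(tolower(g), "_", sprintf("%02d", s))
      probes <- if (spec$n_trials == n) sample(n) else
        sample.int(n, spec$n_trials, replace = spec$n_trials > n)
      for (b in probes) {
        correct <- b                     # designated context of bird b
        others <- setdiff(seq_len(n), correct)
        opts <- c(correct, sample(others, spec$n_options - 1))
        chosen <- if (stats::runif(1) < spec$p_correct) correct else
          sample_error_choice(setdiff(opts, correct), correct, n, lam)
        rows[[length(rows) + 1]] <- list(subject = sid, group = g,
                                         probe_bird = b,
                                         options = paste(sort(opts), collapse = ";"),
                                         chosen = chosen, correct = correct)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Expected overgeneralisation score under the error kernel
#'
#' Closed-form expectation of [overgeneralisation_errors()] for the
#' generator's error model, by exhaustive enumeration of option-set
#' compositions: used to choose spread parameters with a known true group
#' gap and as the oracle for null calibration (`lambda = 0` gives 0).
#'
#' @param lambda Spread parameter.
#' @param n_nodes Ring size.
#' @param n_options Option-set size.
#' @return Expected score (percentage points).
#' @export
expected_og_errors <- function(lambda, n_nodes = 11, n_options = 6) {
  n <- n_nodes
  sets <- utils::combn(2:n, n_options - 1)   # correct cue fixed at node 1
  contrib <- apply(sets, 2, function(s) {
    d <- link_distance(rep(1L, length(s)), s, n)
    if (!any(d == 1) || !any(d > 1)) return(NA_real_)  # not an opportunity set
    w <- exp(-lambda * (d - 1))
    p <- w / sum(w)
    sum(p[d == 1]) / sum(d == 1) - sum(p[d > 1]) / sum(d > 1)
  })
  # error trials fall on opportunity sets with the sets' own frequency;
  # the score conditions on opportunity trials only
  100 * mean(contrib, na.rm = TRUE)
}

#' Specification for synthetic pupil recordings
#'
#' Emulates task pupillometry: a 500 Hz trace per subject with slow baseline
#' drift, a phasic event-locked dilation for every stimulus, an additional
#' oddball-only sustained (tonic) component over a late window whose
#' amplitude may differ between groups, white measurement noise, and random
#' blink gaps (some long enough to violate the trial QC rule).
#'
#' @param n_subjects Subjects per group.
#' @param n_trials Trials per subject (91%/9% regular/oddball mix).
#' @param p_oddball Oddball proportion.
#' @param event_interval_s Spacing between event onsets (s).
#' @param fs Sampling rate (Hz).
#' @param baseline Mean pupil size (arbitrary units).
#' @param drift_amp Amplitude of the slow sinusoidal baseline drift (au).
#' @param phasic_amp Peak of the phasic response (au, all stimuli).
#' @param phasic_amp_oddball Extra phasic peak for oddballs (au).
#' @param tonic_amp Named vector of tonic oddball amplitudes per group (au)
#'   over `tonic_window`.
#' @param tonic_window Window (s, post-onset) of the tonic component.
#' @param noise_sd White noise SD (au).
#' @param blink_rate Blinks per second.
#' @param blink_ms Mean blink duration (ms).
#' @return A list of class `pupil_gen_spec`.
#' @export
pupil_gen_spec <- function(n_subjects = 15, n_trials = 110, p_oddball = 0.09,
                           event_interval_s = 12, fs = 500,
                           baseline = 1000, drift_amp = 20,
                           phasic_amp = 15, phasic_amp_oddball = 15,
                           tonic_amp = c(ATX = 0, PLC = 0),
                           tonic_window = c(6, 10),
                           noise_sd = 10, blink_rate = 0.1, blink_ms = 250) {
  stopifnot(p_oddball > 0, p_oddball < 1, fs > 0,
            all(is.finite(c(baseline, drift_amp, phasic_amp,
                            phasic_amp_oddball, tonic_amp, noise_sd))))
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 p_oddball = p_oddball, event_interval_s = event_interval_s,
                 fs = fs, baseline = baseline, drift_amp = drift_amp,
                 phasic_amp = phasic_amp,
                 phasic_amp_oddball = phasic_amp_oddball,
                 tonic_amp = tonic_amp, tonic_window = tonic_window,
                 noise_sd = noise_sd, blink_rate = blink_rate,
                 blink_ms = blink_ms),
            class = "pupil_gen_spec")
}

# canonical phasic pupil impulse response (Erlang-style kernel, peak at t_max)
phasic_kernel <- function(t, t_max = 0.93, n = 10.1) {
  k <- t^n * exp(-n * t / t_max)
  k / max(k)
}

gen_pupil_subject <- function(spec, group) {
  fs <- spec$fs
  n_ev <- spec$n_trials
  lead <- 2
  dur <- lead + n_ev * spec$event_interval_s + 2
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  onset_t <- lead + (seq_len(n_ev) - 1) * spec$event_interval_s
  onset_i <- round(onset_t * fs) + 1L
  n_odd <- max(1L, round(spec$p_oddball * n_ev))
  cond <- rep("regular", n_ev)
  cond[sample.int(n_ev, n_odd)] <- "oddball"
  x <- spec$baseline +
    spec$drift_amp * sin(2 * pi * t / (dur / 3) + stats::runif(1, 0, 2 * pi))
  kt <- seq(0, 4, by = 1 / fs)
  kern <- phasic_kernel(kt)
  tw <- spec$tonic_window
  tonic_t <- seq(0, tw[2], by = 1 / fs)
  ramp <- stats::plogis((tonic_t - tw[1]) / 0.3)   # smooth onset at tw[1]
  tamp <- spec$tonic_amp[[group]] %||% 0
  for (k in seq_len(n_ev)) {
    i <- onset_i[k]
    amp <- spec$phasic_amp +
      if (cond[k] == "oddball") spec$phasic_amp_oddball else 0
    j <- i:min(n, i + length(kern) - 1L)
    x[j] <- x[j] + amp * kern[seq_along(j)]
    if (cond[k] == "oddball" && tamp != 0) {
      j2 <- i:min(n, i + length(ramp) - 1L)
      x[j2] <- x[j2] + tamp * ramp[seq_along(j2)]
    }
  }
  x <- x + stats::rnorm(n, 0, spec$noise_sd)
  missing <- integer(n)
  n_blinks <- stats::rpois(1, spec$blink_rate * dur)
  if (n_blinks > 0) {
    starts <- sort(stats::runif(n_blinks, 0, dur - 2))
    lens <- stats::rexp(n_blinks, rate = 1000 / spec$blink_ms)
    for (b in seq_len(n_blinks)) {
      i0 <- round(starts[b] * fs) + 1L
      i1 <- min(n, i0 + round(lens[b] * fs))
      missing[i0:i1] <- 1L
    }
  }
  event <- character(n)
  event[] <- ""
  event[onset_i] <- cond
  tibble::tibble(time_s = t, pupil = x, missing = missing,
                 event = event, block = 1L)
}

#' Generate synthetic pupil recordings for a two-group cohort
#'
#' @param spec A [pupil_gen_spec()].
#' @param groups Group labels (each gets `spec$n_subjects` subjects).
#' @return A list with `recordings` (list of tibbles), `groups` (character),
#'   and `truth` (the spec, including the tonic effect window).
#'   Reproducible under [set.seed()].
#' @export
gen_pupil <- function(spec = pupil_gen_spec(), groups = c("ATX", "PLC")) {
  recs <- list(); gl <- character(0)
  for (g in groups) {
    for (s in seq_len(spec$n_subjects)) {
      recs[[paste0(tolower(g), "_", sprintf("%02d", s))]] <-
        gen_pupil_subject(spec, g)
      gl <- c(gl, g)
    }
  }
  list(recordings = recs, groups = gl, truth = spec)
}

#' Generate blinding guesses
#'
#' Bernoulli correct-guess indicators per subject and arm.
#'
#' @param n_per_group Subjects per arm.
#' @param p_correct_guess Probability of guessing the assigned treatment.
#' @param arms Arm labels.
#' @return A tibble: `arm`, `guess_correct`.
#' @export
gen_blinding <- function(n_per_group, p_correct_guess, arms = c("ATX", "PLC")) {
  stopifnot(p_correct_guess >= 0, p_correct_guess <= 1)
  tibble::tibble(
    arm = rep(arms, each = n_per_group),
    guess_correct = stats::runif(n_per_group * length(arms)) < p_correct_guess)
}

#' Read and write behavioural trial tables
#'
#' The on-disk schema is CSV with columns `subject`, `group`, `probe_bird`,
#' `options` (semicolon-joined context ids), `chosen`, `correct`.
#'
#' @param trials A trial tibble.
#' @param path CSV path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   tibble.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(options = "character")))
}
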