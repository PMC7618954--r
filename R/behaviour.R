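#' Ring association task
#'
#' The task structure: `n_nodes` bird stimuli arranged on a ring, with the
#' pair `(i, i + 1 mod n)` presented in context `i`. Every bird therefore
#' belongs to exactly two contexts; context `i` is the "designated" correct
#' context of bird `i` (the room shared with its clockwise neighbour), and
#' the alternate context sits at link distance 1.
#'
#' @param n_nodes Number of ring nodes (birds and contexts); at least 4.
#' @return A list of class `ring_task`.
#' @export
#' @examples
#' ring_task(11)
ring_task <- function(n_nodes = 11) {
  if (n_nodes < 4) stop("a ring task needs at least 4 nodes")
  structure(list(
    n_nodes = as.integer(n_nodes),
    contexts = tibble::tibble(
      context = seq_len(n_nodes),
      bird_a = seq_len(n_nodes),
      bird_b = seq_len(n_nodes) %% n_nodes + 1L)),
    class = "ring_task")
}

#' @rdname ring_task
#' @param seed Optional seed (the task itself is deterministic; accepted for
#'   a uniform generator interface).
#' @export
gen_task <- function(n_nodes = 11, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ring_task(n_nodes)
}

#' Link distance on the ring
#'
#' Number of links between two nodes measured along the shorter ring
#' direction: `min(|i - j|, n - |i - j|)`.
#'
#' @param i,j Node ids in `1..n_nodes` (vectorised).
#' @param n_nodes Ring size.
#' @return Integer distance(s) in `0..floor(n_nodes / 2)`.
#' @export
#' @examples
#' link_distance(1, 7, 11)
link_distance <- function(i, j, n_nodes) {
  if (any(i < 1 | i > n_nodes | j < 1 | j > n_nodes))
    stop("node ids must be in 1..n_nodes")
  d <- abs(i - j)
  pmin(d, n_nodes - d)
}

#' Rank proximity of a choice
#'
#' The rank of a chosen cue relative to the correct cue: a correct choice
#' ranks 1, a cue one link away ranks 2, and so on
#' (`link_distance(correct, chosen) + 1`).
#'
#' @param correct,chosen Cue ids (vectorised).
#' @param task A [ring_task()].
#' @return Integer rank(s) >= 1.
#' @export
#' @examples
#' task <- ring_task(11)
#' rank_proximity(1, 2, task)  # neighbouring context ranks 2
rank_proximity <- function(correct, chosen, task) {
  link_distance(correct, chosen, task$n_nodes) + 1L
}

parse_options <- function(options) {
  if (is.list(options)) return(lapply(options, as.integer))
  lapply(strsplit(as.character(options), ";", fixed = TRUE), as.integer)
}

check_trials <- function(trials) {
  need <- c("probe_bird", "options", "chosen", "correct")
  if (!all(need %in% names(trials)))
    stop("trials need columns ", paste(need, collapse = ", "))
  opts <- parse_options(trials$options)
  ok <- mapply(function(o, ch, co) (ch %in% o) && (co %in% o),
               opts, trials$chosen, trials$correct)
  if (!all(ok)) stop("chosen and correct cues must be members of the option set")
  opts
}

#' Overgeneralisation error score
#'
#' For one subject's trials on the implicit (bird-to-context) test, the
#' percentage-point excess of proximal over distal errors:
#' \deqn{100 \times \frac{\sum_t prox_t / Nprox_t - \sum_t dist_t / Ndist_t}
#'   {N_{opportunity}}}
#' where a proximal cue sits at link distance 1 from the correct cue, a
#' distal cue is any other incorrect cue, `Nprox`/`Ndist` count such cues in
#' the trial's option set, and the sums and the denominator run over error
#' trials whose option set contains at least one cue of each class
#' ("opportunity" trials). Uniform random errors score 0 in expectation;
#' always-proximal scores +100, always-distal -100.
#'
#' @param trials A data frame of one subject's trials with columns
#'   `probe_bird`, `options` (semicolon-joined ids or a list column),
#'   `chosen`, `correct`.
#' @param task A [ring_task()].
#' @return A percentage in `[-100, 100]`, or `NA` (with a warning) when no
#'   opportunity trial exists.
#' @export
overgeneralisation_errors <- function(trials, task) {
  opts <- check_trials(trials)
  err <- trials$chosen != trials$correct
  if (!any(err)) {
    warning("no error trials: overgeneralisation score undefined")
    return(NA_real_)
  }
  num_p <- 0; num_d <- 0; n_opp <- 0L
  for (t in which(err)) {
    o <- opts[[t]]
    co <- trials$correct[t]
    wrong <- o[o != co]
    d <- link_distance(rep(co, length(wrong)), wrong, task$n_nodes)
    n_prox <- sum(d == 1); n_dist <- sum(d > 1)
    if (n_prox == 0 || n_dist == 0) next
    n_opp <- n_opp + 1L
    chosen_d <- link_distance(co, trials$chosen[t], task$n_nodes)
    if (chosen_d == 1) num_p <- num_p + 1 / n_prox
    else num_d <- num_d + 1 / n_dist
  }
  if (n_opp == 0L) {
    warning("no opportunity trials: overgeneralisation score undefined")
    return(NA_real_)
  }
  100 * (num_p - num_d) / n_opp
}

#' Mean rank proximity of errors
#'
#' Mean of [rank_proximity()] over a subject's error trials: 2 when every
#' error picks an immediate ring neighbour of the correct cue, larger when
#' errors land further away.
#'
#' @inheritParams overgeneralisation_errors
#' @return Mean rank (>= 2), or `NA` (with a warning) when there are no
#'   error trials.
#' @export
mean_rank_proximity <- function(trials, task) {
  check_trials(trials)
  err <- trials$chosen != trials$correct
  if (!any(err)) {
    warning("no error trials: mean rank proximity undefined")
    return(NA_real_)
  }
  mean(rank_proximity(trials$correct[err], trials$chosen[err], task))
}

#' Score a cohort of subjects
#'
#' Per-subject behavioural metrics for a trial table covering many subjects.
#'
#' @param trials A data frame with columns `subject`, `group`, `probe_bird`,
#'   `options`, `chosen`, `correct`.
#' @param task A [ring_task()].
#' @return A tibble with one row per subject: `subject`, `group`,
#'   `accuracy`, `og_errors`, `mean_rank_prox`.
#' @export
score_subjects <- function(trials, task) {
  stopifnot(all(c("subject", "group") %in% names(trials)))
  trials |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        accuracy = mean(df$chosen == df$correct),
        og_errors = suppressWarnings(overgeneralisation_errors(df, task)),
        mean_rank_prox = suppressWarnings(mean_rank_proximity(df, task)))
    }) |>
    dplyr::ungroup()
}

#' Topological distance of a ring reconstruction
#'
#' Scores a participant's reconstruction of the ring. Each row of
#' `arrangement` gives, for one bird, the bird the participant placed as its
#' clockwise neighbour and the context the pair was placed in. A correct
#' pairing scores 1, a pairing one link off scores 2, and so on; the metric
#' is the mean score over all bird-bird and bird-context placements.
#'
#' @param arrangement A data frame with columns `bird`, `next_bird`,
#'   `context`, one row per bird.
#' @param task A [ring_task()].
#' @return Mean rank score >= 1.
#' @export
topological_distance <- function(arrangement, task) {
  need <- c("bird", "next_bird", "context")
  if (!all(need %in% names(arrangement)))
    stop("arrangement needs columns ", paste(need, collapse = ", "))
  n <- task$n_nodes
  if (!setequal(arrangement$bird, seq_len(n)))
    stop("incomplete arrangement: every bird must be placed exactly once")
  true_next <- arrangement$bird %% n + 1L
  bb <- link_distance(arrangement$next_bird, true_next, n) + 1
  bs <- link_distance(arrangement$context, arrangement$bird, n) + 1
  mean(c(bb, bs))
}

#' Bang's blinding index
#'
#' Per treatment arm, `BI = 2 p_correct - 1` among respondents: 1 when every
#' guess of the assigned treatment was correct (complete unblinding), -1 when
#' every guess was wrong, 0 under random guessing. `|BI| <= 0.2` is
#' classified as successful blinding.
#'
#' @param responses A data frame with columns `arm` and `guess_correct`
#'   (logical), one row per respondent.
#' @return A tibble per arm: `arm`, `n`, `bi`, `blinded`.
#' @export
bangs_blinding_index <- function(responses) {
  stopifnot(all(c("arm", "guess_correct") %in% names(responses)))
  if (nrow(responses) == 0) stop("no responses: blinding index undefined")
  responses |>
    dplyr::group_by(arm = .data$arm) |>
    dplyr::summarise(n = dplyr::n(),
                     bi = 2 * mean(.data$guess_correct) - 1,
                     .groups = "drop") |>
    dplyr::mutate(blinded = abs(.data$bi) <= 0.2)
}

#' Chance level of the mean rank proximity
#'
#' Exhaustive enumeration of all option-set compositions (the correct cue
#' plus `n_options - 1` of the remaining contexts, uniformly) under uniform
#' random errors: the expected mean rank of an erroneously chosen cue. Used
#' as the chance marker against which observed mean rank proximity is
#' compared.
#'
#' @param task A [ring_task()].
#' @param n_options Option-set size (default 6).
#' @return The chance mean rank (a scalar).
#' @export
chance_mean_rank <- function(task, n_options = 6) {
  n <- task$n_nodes
  others <- 2:n                       # distances are translation invariant
  sets <- utils::combn(others, n_options - 1)
  ranks <- apply(sets, 2, function(s)
    mean(link_distance(rep(1L, length(s)), s, n) + 1))
  mean(ranks)
}
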