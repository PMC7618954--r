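# build a trial tibble from explicit choices
make_trials <- function(probe, options, chosen, correct,
                        subject = "s1", group = "PLC") {
  tibble::tibble(
    subject = subject, group = group, probe_bird = probe,
    options = vapply(options, function(o) paste(o, collapse = ";"), character(1)),
    chosen = chosen, correct = correct)
}

# a subject who always picks an error at a given policy on every trial
policy_trials <- function(task, policy = c("proximal", "distal", "uniform"),
                          n_trials = 200, seed = 1) {
  policy <- match.arg(policy)
  set.seed(seed)
  n <- task$n_nodes
  rows <- lapply(seq_len(n_trials), function(i) {
    correct <- sample.int(n, 1)
    prox <- (correct %% n) + 1                      # one proximal cue
    far <- ((correct + floor(n / 2) - 1) %% n) + 1  # one maximally distal cue
    if (policy == "uniform") {
      opts <- c(correct, sample(setdiff(seq_len(n), correct), 5))
    } else {
      # single proximal / single distal sets make the +/-100 bounds attainable
      opts <- if (policy == "proximal")
        c(correct, prox, sample(setdiff(seq_len(n), c(correct, prox - 1, prox,
                                                      correct - 1 + n * (correct == 1))), 4))
      else c(correct, prox, far)
    }
    wrong <- setdiff(opts, correct)
    d <- link_distance(rep(correct, length(wrong)), wrong, n)
    pick <- switch(policy,
      proximal = wrong[which(d == 1)[1]],
      distal = wrong[which.max(d)],
      uniform = wrong[sample.int(length(wrong), 1)])
    if (is.na(pick)) return(NULL)
    list(probe = correct, opts = list(opts), chosen = pick, correct = correct)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  make_trials(vapply(rows, function(r) r$probe, numeric(1)),
              lapply(rows, function(r) r$opts[[1]]),
              vapply(rows, function(r) r$chosen, numeric(1)),
              vapply(rows, function(r) r$correct, numeric(1)))
}
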