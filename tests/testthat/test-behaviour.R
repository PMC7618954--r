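task11 <- ring_task(11)

test_that("link distance is the shorter way around the ring", {
  expect_equal(link_distance(1, 1, 11), 0)
  expect_equal(link_distance(1, 2, 11), 1)
  expect_equal(link_distance(1, 7, 11), 5)
  # brute force over both directions for every pair
  brute <- function(i, j, n) min((i - j) %% n, (j - i) %% n)
  for (i in 1:11) for (j in 1:11)
    expect_equal(link_distance(i, j, 11), brute(i, j, 11))
  expect_error(link_distance(0, 3, 11), "node ids")
})

test_that("rank proximity follows the worked ranking examples", {
  # probe bird 1: its designated context is A (=1); context B (=2) ranks 2,
  # context D (=4) ranks 4
  expect_equal(rank_proximity(1, 2, task11), 2)
  expect_equal(rank_proximity(1, 4, task11), 4)
  expect_equal(rank_proximity(5, 5, task11), 1)
})

test_that("overgeneralisation score hits its closed-form anchors", {
  # every error proximal on opportunity trials -> +100
  expect_equal(overgeneralisation_errors(policy_trials(task11, "proximal"), task11), 100)
  # every error maximally distal -> -100
  expect_equal(overgeneralisation_errors(policy_trials(task11, "distal"), task11), -100)
  # all-correct subject: undefined, distinct from 0
  tr <- make_trials(1, list(c(1, 2, 4, 6, 8, 10)), 1, 1)
  expect_warning(v <- overgeneralisation_errors(tr, task11), "undefined")
  expect_true(is.na(v))
  # chosen cue must be in the option set
  bad <- make_trials(1, list(c(1, 2, 4, 6, 8, 10)), 3, 1)
  expect_error(overgeneralisation_errors(bad, task11), "option set")
})

test_that("uniform random errors score near zero overgeneralisation", {
  tr <- policy_trials(task11, "uniform", n_trials = 10000, seed = 3)
  expect_lt(abs(overgeneralisation_errors(tr, task11)), 2)
})

test_that("mean rank proximity spans [2, 6] on an 11-ring and matches chance", {
  expect_equal(mean_rank_proximity(policy_trials(task11, "proximal"), task11), 2)
  expect_equal(mean_rank_proximity(policy_trials(task11, "distal"), task11), 6)
  tr <- policy_trials(task11, "uniform", n_trials = 20000, seed = 4)
  chance <- chance_mean_rank(task11)
  expect_equal(mean_rank_proximity(tr, task11), chance, tolerance = 0.02)
  expect_warning(v <- mean_rank_proximity(
    make_trials(1, list(c(1, 2, 4, 6, 8, 10)), 1, 1), task11), "no error")
  expect_true(is.na(v))
})

test_that("chance mean rank agrees with a direct Monte-Carlo oracle", {
  set.seed(9)
  mc <- replicate(50000, {
    opts <- c(1, sample(2:11, 5))
    wrong <- opts[opts != 1]
    link_distance(1, wrong[sample.int(5, 1)], 11) + 1
  })
  expect_equal(chance_mean_rank(task11), mean(mc), tolerance = 0.02)
})

test_that("topological distance scores reconstructions per the ranking rule", {
  n <- 11
  perfect <- tibble::tibble(bird = 1:n, next_bird = (1:n) %% n + 1, context = 1:n)
  expect_equal(topological_distance(perfect, task11), 1)
  # bird 1 placed next to bird 3 scores 2 for that pairing
  one_off <- perfect
  one_off$next_bird[1] <- 3
  expect_equal(topological_distance(one_off, task11), 1 + 1 / (2 * n))
  expect_error(topological_distance(perfect[-1, ], task11), "incomplete")
  # random arrangements sit near the permutation chance level
  set.seed(6)
  vals <- replicate(300, {
    arr <- tibble::tibble(bird = 1:n, next_bird = sample(n), context = sample(n))
    topological_distance(arr, task11)
  })
  # chance: mean rank of a uniform placement = mean link distance + 1
  chance <- mean(link_distance(rep(1, n), 1:n, n)) + 1
  expect_equal(mean(vals), chance, tolerance = 0.05)
})

test_that("Bang's blinding index hits its anchors and classification", {
  all_right <- tibble::tibble(arm = "ATX", guess_correct = rep(TRUE, 10))
  all_wrong <- tibble::tibble(arm = "ATX", guess_correct = rep(FALSE, 10))
  half <- tibble::tibble(arm = "PLC", guess_correct = rep(c(TRUE, FALSE), 5))
  expect_equal(bangs_blinding_index(all_right)$bi, 1)
  expect_equal(bangs_blinding_index(all_wrong)$bi, -1)
  h <- bangs_blinding_index(half)
  expect_equal(h$bi, 0)
  expect_true(h$blinded)
  expect_false(bangs_blinding_index(all_right)$blinded)
  expect_error(bangs_blinding_index(half[0, ]), "no responses")
})

test_that("score_subjects returns one tidy row per subject", {
  set.seed(2)
  tr <- gen_choices(behaviour_gen_spec(n_subjects = 3, n_trials = 11))
  sc <- score_subjects(tr, task11)
  expect_equal(nrow(sc), 6)
  expect_setequal(names(sc),
                  c("subject", "group", "accuracy", "og_errors", "mean_rank_prox"))
  expect_true(all(sc$accuracy >= 0 & sc$accuracy <= 1))
})

test_that("overgeneralisation and mean rank proximity are negatively coupled", {
  set.seed(8)
  spec <- behaviour_gen_spec(n_subjects = 40, n_trials = 44,
                             lambda_atx = 2, lambda_plc = 0.2)
  sc <- score_subjects(gen_choices(spec), task11)
  sc <- sc[stats::complete.cases(sc[, c("og_errors", "mean_rank_prox")]), ]
  rho <- stats::cor(sc$og_errors, sc$mean_rank_prox, method = "spearman")
  expect_lt(rho, -0.5)
})
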