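flat_recording <- function(n_s = 60, fs = 500, value = 1000,
                           events = seq(5, n_s - 12, by = 12)) {
  n <- n_s * fs
  rec <- tibble::tibble(
    time_s = seq_len(n) / fs, pupil = value, missing = 0L,
    event = "", block = 1L)
  idx <- round(events * fs)
  rec$event[idx] <- rep(c("regular", "regular", "oddball"),
                        length.out = length(idx))
  rec
}

test_that("preprocessing leaves a constant trace unchanged and interpolates gaps", {
  rec <- flat_recording(20)
  out <- pupil_preprocess(rec)
  expect_equal(out$pupil, rec$pupil, tolerance = 1e-12)

  # a 200 ms blink is bridged by the straight line between flanking samples
  rec2 <- flat_recording(20)
  rec2$pupil <- 1000 + 10 * rec2$time_s     # linear trend
  gap <- 3000:3100
  rec2$missing[gap] <- 1L
  rec2$pupil[gap] <- 0
  out2 <- pupil_preprocess(rec2, kernel_ms = 1e-6)  # negligible smoothing
  expect_equal(out2$pupil[gap], 1000 + 10 * out2$time_s[gap], tolerance = 1e-6)

  rec3 <- flat_recording(20)
  rec3$missing[1:(nrow(rec3) * 0.6)] <- 1L
  expect_error(pupil_preprocess(rec3), "unusable")
})

test_that("Gaussian smoothing attenuates an impulse by the kernel's gain", {
  rec <- flat_recording(20)
  spike_at <- 5000
  rec$pupil[spike_at] <- rec$pupil[spike_at] + 100
  out <- pupil_preprocess(rec, kernel_ms = 120)
  fs <- 500
  sd_samp <- 120 / 1000 * fs
  expected_peak <- 100 * stats::dnorm(0, sd = sd_samp) /
    sum(stats::dnorm(seq(-ceiling(4 * sd_samp), ceiling(4 * sd_samp)), sd = sd_samp))
  expect_equal(out$pupil[spike_at] - 1000, expected_peak, tolerance = 1e-6)
  # fwhm convention narrows the kernel, attenuating less
  out_fwhm <- pupil_preprocess(rec, kernel_ms = 120, kernel_mode = "fwhm")
  expect_gt(out_fwhm$pupil[spike_at], out$pupil[spike_at])
})

test_that("epoching applies QC rules, normalisation and baseline correction", {
  rec <- flat_recording(130)
  ep <- epoch_and_qc(rec, window = c(-0.25, 10))
  expect_s3_class(ep, "epoch_set")
  expect_equal(ep$n_dropped, 0)
  expect_false(ep$excluded)
  # flat trace: all normalised, baseline-corrected epochs identically 0
  expect_true(all(abs(ep$data) < 1e-10))
  # baseline window mean is 0 for every retained epoch
  bsel <- ep$times >= -0.25 & ep$times < 0
  expect_true(all(abs(rowMeans(ep$data[, bsel])) < 1e-10))

  # scaling invariance of the percent-of-block-mean normalisation
  rec_mod <- flat_recording(130)
  set.seed(1)
  rec_mod$pupil <- 1000 + 50 * sin(rec_mod$time_s) + rnorm(nrow(rec_mod))
  rec_scaled <- rec_mod
  rec_scaled$pupil <- rec_mod$pupil * 3.7
  e1 <- epoch_and_qc(rec_mod)
  e2 <- epoch_and_qc(rec_scaled)
  expect_equal(e1$data, e2$data, tolerance = 1e-10)

  expect_error(epoch_and_qc(flat_recording(130, events = numeric(0))), "no events")
})

test_that("trials losing >1000 ms are dropped and bad subjects flagged", {
  rec <- flat_recording(130)
  fs <- 500
  onsets <- which(rec$event != "")
  # corrupt 60% of trials with a 1.2 s gap inside the epoch
  bad <- onsets[seq_len(ceiling(0.6 * length(onsets)))]
  for (o in bad) rec$missing[o + seq_len(round(1.2 * fs))] <- 1L
  rec <- pupil_preprocess(rec)
  ep <- epoch_and_qc(rec)
  expect_equal(ep$n_dropped, length(bad))
  expect_true(ep$excluded)
  # a 0.5 s gap is tolerated
  rec2 <- flat_recording(130)
  rec2$missing[onsets[1] + seq_len(round(0.5 * fs))] <- 1L
  ep2 <- epoch_and_qc(pupil_preprocess(rec2))
  expect_equal(ep2$n_dropped, 0)
})

test_that("oddball contrast is the condition-mean difference", {
  rec <- flat_recording(130)
  fs <- 500
  onsets <- which(rec$event != "")
  odd <- onsets[rec$event[onsets] == "oddball"]
  # inject a bump only on oddball trials
  for (o in odd) rec$pupil[o + 1:fs] <- rec$pupil[o + 1:fs] + 30
  ep <- epoch_and_qc(rec)
  ctr <- oddball_contrast(ep)
  t_in <- ep$times > 0.1 & ep$times < 1.9   # bump region (post-smoothing-free)
  expect_gt(mean(ctr[ep$times > 0.2 & ep$times < 1.8]), 1)
  expect_lt(max(abs(ctr[ep$times > 5])), 1e-8)

  ep0 <- epoch_and_qc(flat_recording(130))
  expect_true(all(abs(oddball_contrast(ep0)) < 1e-10))

  ep_no_odd <- ep0
  ep_no_odd$condition[ep_no_odd$condition == "oddball"] <- "regular"
  expect_error(oddball_contrast(ep_no_odd), "no retained trials")
})

test_that("cluster permutation finds an injected group difference and not a null one", {
  set.seed(21)
  T_ <- 200
  times <- seq(0, 10, length.out = T_)
  nA <- 12; nB <- 12
  noise <- function(n) t(replicate(n, as.numeric(stats::filter(rnorm(T_ + 20), rep(1/5, 5), sides = 2))[10 + seq_len(T_)]))
  A <- noise(nA); B <- noise(nB)
  null_test <- cluster_permutation(A, B, times, n_perm = 500)
  expect_true(all(!null_test$clusters$significant) || nrow(null_test$clusters) == 0)

  effect <- 3 * (times > 6 & times < 10)
  A2 <- A + matrix(effect, nA, T_, byrow = TRUE)
  alt_test <- cluster_permutation(A2, B, times, n_perm = 500)
  sig <- alt_test$clusters[alt_test$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_lt(min(sig$start_s), 10)
  expect_gt(max(sig$end_s), 6)

  expect_error(cluster_permutation(A[, 1:10], B, n_perm = 10), "time grid")
  expect_error(cluster_permutation(A[1, , drop = FALSE], B, n_perm = 10),
               "2 subjects")
})

test_that("identical groups give no significant clusters", {
  set.seed(5)
  X <- matrix(rnorm(10 * 50), 10)
  out <- cluster_permutation(X, X + matrix(rnorm(500, 0, 1e-8), 10), n_perm = 200)
  expect_true(nrow(out$clusters) == 0 || all(!out$clusters$significant))
})

test_that("pipeline is deterministic given a seed", {
  set.seed(33)
  gp <- gen_pupil(pupil_gen_spec(n_subjects = 3, n_trials = 12,
                                 tonic_amp = c(ATX = 15, PLC = 0)))
  set.seed(100); r1 <- pupil_pipeline(gp$recordings, gp$groups, n_perm = 100)
  set.seed(100); r2 <- pupil_pipeline(gp$recordings, gp$groups, n_perm = 100)
  expect_identical(r1$test$clusters, r2$test$clusters)
})
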