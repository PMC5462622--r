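test_that("cue schedule matches the digit-cycling design", {
  d <- task_design()          # 8 s blocks, 32 s cycle, 8 cycles, digits 2:5
  run <- simulate_fmri_run(sim_grid(c(2, 2, 1)), d, seed = 1)
  expect_equal(nrow(run$cues), 32)                       # 4 digits x 8 cycles
  expect_equal(as.integer(table(run$cues$digit)), rep(8L, 4))  # 8 per digit
  expect_length(run$press_cues, 256)                     # 1 Hz x 8 s x 32 blocks
  # backward runs reverse the digit order within the cycle
  db <- task_design(direction = "backward")
  runb <- simulate_fmri_run(sim_grid(c(2, 2, 1)), db, seed = 1)
  expect_equal(runb$cues$digit[1:4], c(5, 4, 3, 2))
  expect_equal(run$cues$digit[1:4], c(2, 3, 4, 5))
})

test_that("zero-noise delta-tuned voxels reproduce the reference model", {
  d <- task_design()
  # lag grid chosen to contain the digit-block onsets (the TR-spaced
  # default need not, since 8 s is not a multiple of the 1.5 s TR)
  lag_grid <- seq(0, 31.5, by = 0.5)
  for (pd in c(2, 4)) {
    g <- sim_grid(c(1, 1, 1), preferred_digit = pd, tuning_width = 1e-4,
                  noise_sd = 0)
    run <- simulate_fmri_run(g, d, seed = 1)
    lag <- (match(pd, 2:5) - 1) * 8
    ref <- build_reference_model(d, lag)
    expect_lt(max(abs(run$img[1, 1, 1, ] - ref)), 1e-10)
    prof <- compute_tuning_profile(run$img[1, 1, 1, ], d, lag_grid)
    expect_equal(prof$lags[which.max(prof$r)], lag)
    expect_equal(max(prof$r), 1, tolerance = 1e-9)
  }
})

test_that("fMRI simulation is seed-deterministic and AR(1) noise is sane", {
  g <- sim_grid(c(3, 2, 1), noise_sd = 0.7, noise_ar1 = 0.4)
  d <- task_design()
  r1 <- simulate_fmri_run(g, d, seed = 99)
  r2 <- simulate_fmri_run(g, d, seed = 99)
  expect_identical(r1$img, r2$img)
  r3 <- simulate_fmri_run(g, d, seed = 100)
  expect_false(identical(r1$img, r3$img))
  # marginal noise SD approximately preserved under AR(1)
  g0 <- sim_grid(c(10, 10, 1), amplitude = 0, noise_sd = 0.7, noise_ar1 = 0.4)
  rn <- simulate_fmri_run(g0, d, seed = 5)
  expect_equal(sd(as.numeric(rn$img)), 0.7, tolerance = 0.05)
})

test_that("TOJ trial simulation follows the observer's logistic", {
  obs <- toj_observer(mu = 0, slope = 50, lapse = 0)
  trials <- simulate_toj_trials(obs, seed = 3)
  expect_equal(nrow(trials), 192)                         # 12 ISIs x 16 trials
  expect_identical(simulate_toj_trials(obs, seed = 3), trials)
  # saturation: far ISI, no lapse
  expect_equal(toj_prob(obs, 1e6), 1)
  expect_error(toj_observer(slope = -1), "positive")
  # large-sample proportions within 3 binomial SEs of the exact logistic
  big <- simulate_toj_trials(obs, trials_per_isi = 10000, seed = 4)
  agg <- aggregate_proportions(big)
  p_true <- toj_prob(obs, agg$isi_ms)
  se <- sqrt(p_true * (1 - p_true) / agg$n_trials)
  expect_true(all(abs(agg$prop_middle_first - p_true) <= 3 * se + 1e-12))
})

test_that("cohort generator matches the structural-equation covariance", {
  truth <- cohort_truth(n_subjects = 5000, path_a = 0.7, path_b = -0.6,
                        path_c_prime = 0, noise_sd_m = 0.3, noise_sd_y = 0.3)
  coh <- simulate_cohort(truth, seed = 8)
  S <- implied_covariance(truth)
  R_imp <- stats::cov2cor(S)
  expect_equal(cor(coh$X, coh$M), R_imp["X", "M"], tolerance = 0.03)
  expect_equal(cor(coh$X, coh$Y), R_imp["X", "Y"], tolerance = 0.03)
  expect_equal(cor(coh$M, coh$Y), R_imp["M", "Y"], tolerance = 0.03)
  # the affine maps to measurement scales preserve correlations
  expect_equal(cor(coh$gaba_cr, coh$jnd), cor(coh$X, coh$Y), tolerance = 1e-12)
  # null mediation: no b or c' paths -> X and Y uncorrelated
  null_truth <- cohort_truth(n_subjects = 5000, path_a = 0.7, path_b = 0,
                             path_c_prime = 0)
  null_coh <- simulate_cohort(null_truth, seed = 9)
  expect_lt(abs(cor(null_coh$X, null_coh$Y)), 0.05)
  expect_identical(simulate_cohort(truth, seed = 8), coh)
})

test_that("raw-level cohort attaches monotone generator links", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 50), seed = 2,
                         raw_level = TRUE)
  # sharper tuning (higher metric) maps to smaller width; larger JND to
  # shallower observer slope
  expect_lte(cor(coh$tuning, coh$tuning_width, method = "spearman"), 0)
  expect_gte(cor(coh$jnd, coh$toj_slope, method = "spearman"), 0.99)
  expect_true(all(coh$tuning_width > 0))
  expect_true(all(coh$toj_slope > 0))
})

test_that("MRS table simulation injects the stated QC failure fraction", {
  tab0 <- simulate_mrs_table(30, qc_fail_fraction = 0, seed = 1)
  expect_equal(nrow(qc_filter(tab0)$excluded), 0)
  expect_equal(max(abs(tab0$gm + tab0$wm + tab0$csf - 1)), 0, tolerance = 1e-9)

  tab <- simulate_mrs_table(100, qc_fail_fraction = 0.2, seed = 7)
  qc <- qc_filter(tab)
  expect_equal(length(unique(qc$excluded$subject)), 20)   # exactly 20 spectra
  expect_identical(simulate_mrs_table(100, qc_fail_fraction = 0.2, seed = 7), tab)
  expect_error(simulate_mrs_table(10, qc_fail_fraction = 1.2), "qc_fail_fraction")
})
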