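test_that("reference model is periodic, normalized and lag-validated", {
  d <- task_design()
  m0 <- build_reference_model(d, 0)
  expect_length(m0, 170)
  expect_equal(sd(m0), 1)
  expect_equal(mean(m0), 0, tolerance = 1e-12)
  expect_equal(cor(m0, build_reference_model(d, 0)), 1)
  # circular boundary: lag just below cycle_s converges to lag 0
  m_eps <- build_reference_model(d, d$cycle_s - 0.1)
  expect_gt(cor(m0, m_eps), 0.995)
  expect_error(build_reference_model(d, d$cycle_s), "lag")
  expect_error(build_reference_model(d, -1), "lag")
})

test_that("plant-and-recover: profile argmax is the planted lag", {
  d <- task_design()
  lag_grid <- default_lag_grid(d)
  models <- lapply(lag_grid, function(l) build_reference_model(d, l))
  for (L in c(0, 7.5, 16.5, 30)) {
    ts <- build_reference_model(d, L)
    prof <- compute_tuning_profile(ts, d, lag_grid, models = models)
    expect_equal(prof$lags[which.max(prof$r)], L)
    expect_equal(max(prof$r), 1, tolerance = 1e-9)
    # sign flip
    prof_neg <- compute_tuning_profile(-ts, d, lag_grid, models = models)
    expect_equal(prof_neg$r[prof_neg$lags == L], -1, tolerance = 1e-9)
  }
  # constant series is flagged, not an error
  prof_const <- compute_tuning_profile(rep(1, d$n_volumes), d, lag_grid,
                                       models = models)
  expect_false(prof_const$ok)
  expect_true(all(is.na(prof_const$r)))
})

test_that("white-noise profiles rarely reach r = 0.5", {
  d <- task_design()
  lag_grid <- seq(0, 31, by = 1)                 # 32 lags
  models <- lapply(lag_grid, function(l) build_reference_model(d, l))
  M <- do.call(cbind, models)
  set.seed(20)
  max_r <- vapply(seq_len(1000), function(i) {
    max(abs(cor(rnorm(d$n_volumes), M)))
  }, numeric(1))
  expect_gte(mean(max_r < 0.5), 0.99)
})

test_that("sinusoid fit recovers noiseless parameters exactly", {
  x <- seq(0, 31.5, by = 1.5)
  y <- 1.0 * sin(2 * pi / 16 * x - 0) + 0
  fit <- fit_sinusoid(list(lags = x, r = y))
  expect_equal(fit$period, 16, tolerance = 1e-6)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$B, 0, tolerance = 1e-6)
  expect_equal(sin(fit$phi), 0, tolerance = 1e-6)  # phase mod 2*pi
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$converged)

  # amplitude/period are unchanged when the same truth is phase-shifted
  y2 <- 0.7 * sin(2 * pi / 16 * x - 1.1) + 0.2
  fit2 <- fit_sinusoid(list(lags = x, r = y2))
  expect_equal(fit2$period, 16, tolerance = 1e-6)
  expect_equal(fit2$a, 0.7, tolerance = 1e-6)
  expect_equal(fit2$B, 0.2, tolerance = 1e-6)

  # constant profile: degenerate, amplitude ~ 0
  fitc <- fit_sinusoid(list(lags = x, r = rep(0.3, length(x))))
  expect_true(fitc$degenerate)
  expect_lt(fitc$a, 1e-6)
  expect_error(fit_sinusoid(list(lags = 1:5, r = rnorm(5))), "8 lag points")
})

test_that("fit optimality: rss never exceeds the grid-search oracle's", {
  x <- seq(0, 31.5, by = 1.5)
  set.seed(31)
  for (i in 1:20) {
    P <- runif(1, 8, 48)
    y <- runif(1, 0.4, 1) * sin(2 * pi / P * x - runif(1, 0, 2 * pi)) +
      rnorm(length(x), sd = 0.15)
    fit <- fit_sinusoid(list(lags = x, r = y), recenter = FALSE)
    oracle <- oracle_grid_sinusoid(x, y, period_range = c(3, 64))
    expect_lte(fit$rss, oracle$rss + 1e-8)
  }
})

test_that("combine_runs averages maps and reduces period error", {
  d <- task_design()
  db <- task_design(direction = "backward")
  g <- sim_grid(c(3, 3, 1), tuning_width = 0.8, noise_sd = 0.4)
  mk <- function(design, seed) {
    fit_tuning_maps(simulate_fmri_run(g, design, seed = seed)$img, design)
  }
  mf <- mk(d, 1)
  # idempotence on identical maps
  same <- combine_runs(mf, mf)
  expect_equal(same$amplitude, mf$amplitude)
  expect_equal(same$period, mf$period)
  # plain mean
  mb <- mk(db, 2)
  comb <- combine_runs(mf, mb)
  both <- comb$converged
  expect_equal(comb$amplitude[both],
               ((mf$amplitude + mb$amplitude) / 2)[both])
  # shape mismatch errors
  g2 <- sim_grid(c(2, 2, 1))
  m2 <- fit_tuning_maps(simulate_fmri_run(g2, d, seed = 1)$img, d)
  expect_error(combine_runs(mf, m2), "shape")

  # variance reduction: combining forward+backward lowers RMSE vs the
  # noise-free period map in most replicates (scaled from 100 to 12 seeds
  # to stay inside the test-time budget)
  g0 <- sim_grid(c(3, 3, 1), tuning_width = 0.8, noise_sd = 0)
  truth_per <- fit_tuning_maps(simulate_fmri_run(g0, d, seed = 1)$img, d)$period
  rmse <- function(a) sqrt(mean((a - truth_per)^2, na.rm = TRUE))
  wins <- vapply(1:12, function(s) {
    f <- mk(d, 100 + s)
    b <- mk(db, 500 + s)
    rmse(combine_runs(f, b)$period) < rmse(f$period)
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("define_roi applies Fisher z + BH and flags planted voxels", {
  amp <- array(0.02, c(5, 5, 2))
  amp[2, 3, 1] <- 0.99
  roi <- define_roi(amp, n_timepoints = 170, alpha = 0.01)
  expect_true(roi$mask[2, 3, 1])
  expect_equal(roi$n_voxels, 1)
  expect_error(define_roi(array(1.2, c(2, 2, 1)), 170), "amplitudes")
  expect_error(define_roi(amp, 170, alpha = 0), "alpha")
  # NA (non-converged) voxels never enter the mask
  amp[1, 1, 1] <- NA
  roi2 <- define_roi(amp, 170)
  expect_false(roi2$mask[1, 1, 1])
})

test_that("tuning metric is 1/mean(period) over the ROI and order-invariant", {
  per <- array(16, c(4, 4, 1))
  mask <- array(TRUE, c(4, 4, 1))
  expect_equal(tuning_metric(per, mask), 0.0625)
  # single-voxel ROI
  per[2, 2, 1] <- 20
  one <- array(FALSE, c(4, 4, 1)); one[2, 2, 1] <- TRUE
  expect_equal(tuning_metric(per, one), 1 / 20)
  # invariant to voxels outside the ROI
  per2 <- per; per2[!one] <- 0
  expect_equal(tuning_metric(per2, one), tuning_metric(per, one))
  # the mean-of-inverses alternative differs for heterogeneous maps
  per3 <- array(c(10, 20), c(2, 1, 1))
  m3 <- array(TRUE, c(2, 1, 1))
  expect_equal(tuning_metric(per3, m3), 1 / 15)
  expect_equal(tuning_metric(per3, m3, aggregate = "mean_inverse"),
               mean(c(1 / 10, 1 / 20)))
  expect_error(tuning_metric(per, array(FALSE, c(4, 4, 1))), "empty ROI")
})

test_that("press metrics: accuracy window and 2-SD outlier rule", {
  cues <- 0:19
  # presses exactly at every cue
  pm <- press_metrics(presses = cues, cues = cues)
  expect_equal(pm$accuracy, 1)
  # one interval 10x all others among 20 is excluded by the 2-SD rule
  presses <- cumsum(c(0, rep(1, 19), 10))
  pm2 <- press_metrics(presses, cues = presses)
  expect_equal(pm2$n_intervals_used, 19)
  expect_equal(pm2$n_outliers, 1)
  expect_equal(pm2$mean_ipi, 1)
  expect_equal(pm2$rate, 1)
  # press 401 ms after the cue is inaccurate
  expect_equal(press_metrics(presses = 0.401, cues = 0)$accuracy, 0)
  expect_equal(press_metrics(presses = 0.400, cues = 0)$accuracy, 1)
  # no presses: flagged rate, zero accuracy
  none <- press_metrics(numeric(0), cues = cues)
  expect_equal(none$accuracy, 0)
  expect_true(is.na(none$rate))
})
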