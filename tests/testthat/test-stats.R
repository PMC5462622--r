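test_that("Pearson p values match the t construction and a permutation oracle", {
  # orthogonal vectors: r = 0 -> p = 1
  x <- c(1, -1, 1, -1, 1, -1)
  y <- c(1, 1, -1, -1, 1, 1)
  res <- pearson_with_p(x, y)
  expect_equal(res$r, 0, tolerance = 1e-12)
  expect_equal(res$p_two_tailed, 1)
  expect_equal(res$fisher_z, 0)
  expect_error(pearson_with_p(rep(1, 6), y), "zero variance")
  # agreement with stats::cor.test on random data
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(15); b <- 0.4 * a + rnorm(15)
    res <- pearson_with_p(a, b)
    ct <- cor.test(a, b)
    expect_equal(res$p_two_tailed, ct$p.value, tolerance = 1e-12)
    # permutation oracle within Monte-Carlo error
    pp <- oracle_perm_cor_p(a, b, n_perm = 4000, seed = i)
    expect_lt(abs(res$p_two_tailed - pp),
              0.03 + 3 * sqrt(pp * (1 - pp) / 4000))
  }
})

test_that("Hittner test: symmetry, validation and tail conventions", {
  h0 <- hittner_test(0.5, 0.5, 0.3, n = 22)
  expect_equal(h0$z_stat, 0)
  expect_equal(h0$p_two_tailed, 1)
  h <- hittner_test(0.676, 0.146, 0.2, n = 22)
  expect_gt(h$z_stat, 0)
  expect_equal(h$p_two_tailed, 2 * h$p_one_tailed)
  # invalid (non-PSD) correlation triple
  expect_error(hittner_test(0.9, -0.9, 0.9, n = 22), "positive semidefinite")
  expect_error(hittner_test(0.5, 0.4, 0.3, n = 5), "n >= 10")
})

test_that("partial correlation matches the residualization construction", {
  set.seed(2)
  x <- rnorm(40); z <- rnorm(40); y <- 0.5 * x + 0.3 * z + rnorm(40)
  pc <- partial_correlation(x, y, z)
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-12)
  # y == covariate -> partial r is 0
  expect_equal(partial_correlation(x, z, z)$r, 0, tolerance = 1e-12)
  # covariate uncorrelated with both -> partial ~ raw (large n)
  set.seed(3)
  a <- rnorm(4000); b <- 0.5 * a + rnorm(4000); w <- rnorm(4000)
  expect_equal(partial_correlation(a, b, w)$r, cor(a, b), tolerance = 0.01)
  expect_error(partial_correlation(x, y, x), "collinear")
})

test_that("conjunction/omnibus verdict follows the compound rule", {
  res <- conjunction_omnibus(c(0.011, 0.02, 0.016), c(0.877, 0.592))
  expect_equal(res$conjunction_statistic, 0.02)
  expect_equal(res$omnibus_statistic, 0.592)
  expect_true(res$reject)
  # singleton lists
  one <- conjunction_omnibus(0.03, 0.5)
  expect_equal(one$conjunction_statistic, 0.03)
  expect_equal(one$omnibus_statistic, 0.5)
  # fails when a predicted correlation is non-significant, or an
  # unpredicted one is significant
  expect_false(conjunction_omnibus(c(0.01, 0.2), 0.5)$reject)
  expect_false(conjunction_omnibus(c(0.01, 0.02), 0.01)$reject)
  expect_error(conjunction_omnibus(c(0, 0.01), 0.5), "p values")
  # monotone: lowering any predicted p never flips reject -> accept
  set.seed(4)
  for (i in 1:20) {
    p_pred <- runif(3); p_un <- runif(2)
    v1 <- conjunction_omnibus(p_pred, p_un)$reject
    p_lower <- p_pred * runif(3)
    v2 <- conjunction_omnibus(p_lower, p_un)$reject
    expect_true(!v1 || v2)
  }
})

test_that("mediation paths and Sobel match an independent OLS oracle", {
  fx <- mediation_fixture()
  med <- mediate(fx$x, fx$m, fx$y, n_boot = 1000, seed = 1)
  ex <- fx$expected
  expect_equal(med$a, ex$a, tolerance = 1e-9)
  expect_equal(med$b, ex$b, tolerance = 1e-9)
  expect_equal(med$c_prime, ex$c_prime, tolerance = 1e-9)
  expect_equal(med$c_total, ex$c_total, tolerance = 1e-9)
  expect_equal(med$indirect, ex$a * ex$b, tolerance = 1e-9)
  expect_equal(med$sobel_z, ex$sobel_z, tolerance = 1e-9)
  expect_equal(med$sobel_p, ex$sobel_p, tolerance = 1e-9)
  expect_true(med$kappa2 >= 0 && med$kappa2 <= 1)
  # total = direct + indirect (OLS identity)
  expect_equal(med$c_total, med$c_prime + med$indirect, tolerance = 1e-9)
})

test_that("bootstrap is seed-reproducible and the null path covers zero", {
  fx <- mediation_fixture()
  m1 <- mediate(fx$x, fx$m, fx$y, n_boot = 1000, seed = 7)
  m2 <- mediate(fx$x, fx$m, fx$y, n_boot = 1000, seed = 7)
  expect_identical(m1$boot_ci, m2$boot_ci)
  m3 <- mediate(fx$x, fx$m, fx$y, n_boot = 1000, seed = 8)
  expect_false(identical(m3$boot_ci, m1$boot_ci))
  # b = 0 in the generating model -> indirect ~ 0, CI covers 0
  truth <- cohort_truth(n_subjects = 1500, path_a = 0.7, path_b = 0,
                        path_c_prime = 0.3)
  coh <- simulate_cohort(truth, seed = 5)
  mn <- mediate(coh$X, coh$M, coh$Y, n_boot = 1000, seed = 5)
  expect_lt(abs(mn$indirect), 0.05)
  expect_true(mn$boot_ci[1] <= 0 && mn$boot_ci[2] >= 0)
})

test_that("r-based statistics are invariant to affine rescaling", {
  fx <- mediation_fixture()
  x2 <- 3 + 2 * fx$x; m2 <- -1 + 0.5 * fx$m; y2 <- 10 + 4 * fx$y
  med1 <- mediate(fx$x, fx$m, fx$y, n_boot = 1000, seed = 3)
  med2 <- mediate(x2, m2, y2, n_boot = 1000, seed = 3)
  expect_equal(med1$sobel_z, med2$sobel_z, tolerance = 1e-9)
  expect_equal(med1$p_m, med2$p_m, tolerance = 1e-9)
  expect_equal(med1$kappa2, med2$kappa2, tolerance = 1e-9)
  h1 <- hittner_test(0.6, 0.2, 0.3, 22)   # already r-based: pure function of r
  expect_equal(h1$z_stat, hittner_test(0.6, 0.2, 0.3, 22)$z_stat)
})

test_that("ICC(A,1) matches the frozen external oracle and its definition", {
  fx <- icc_fixture()
  res <- icc_a1(fx$tab)
  expect_equal(res$icc, fx$expected_icc, tolerance = 1e-9)
  expect_equal(round(c(res$ci_low, res$ci_high), 2), fx$expected_ci_2dp)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
  # identical sessions -> ICC = 1
  same <- cbind(fx$tab[, 1], fx$tab[, 1])
  expect_equal(icc_a1(same)$icc, 1)
  # absolute agreement: a constant session offset lowers the ICC
  shifted <- fx$tab; shifted[, 2] <- shifted[, 2] + 1.5
  expect_lt(icc_a1(shifted)$icc, res$icc)
  expect_error(icc_a1(rbind(fx$tab, c(NA, 1))), "incomplete")
})
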