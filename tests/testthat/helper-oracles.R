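# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Brute-force sinusoid fit: dense grid over period and phase; amplitude and
# offset by closed-form simple regression of y on sin(w*x - phi). Returns the
# best candidate. Structurally different from the package's profiled solver
# (no joint sin/cos linear system).
oracle_grid_sinusoid <- function(x, y, period_range, period_step = 0.25,
                                 n_phase = 720) {
  periods <- seq(period_range[1], period_range[2], by = period_step)
  phases <- seq(0, 2 * pi, length.out = n_phase + 1)[-(n_phase + 1)]
  cph <- cos(phases); sph <- sin(phases)
  best <- list(rss = Inf)
  my <- mean(y)
  yc <- y - my
  for (P in periods) {
    w <- 2 * pi / P
    sv <- sin(w * x); cv <- cos(w * x)
    S <- outer(sv, cph) - outer(cv, sph)        # points x phases
    Sc <- sweep(S, 2, colMeans(S))
    vs <- colSums(Sc^2)
    a <- ifelse(vs > 1e-12, colSums(Sc * yc) / vs, 0)
    rss <- sum(yc^2) - a^2 * vs                 # regression identity
    j <- which.min(rss)
    if (rss[j] < best$rss) {
      best <- list(rss = rss[j], period = P, phi = phases[j], a = a[j],
                   B = my - a[j] * mean(S[, j]))
    }
  }
  best
}

# Permutation p value for a Pearson correlation (two-tailed, by |r|).
oracle_perm_cor_p <- function(x, y, n_perm = 4000, seed = 1) {
  set.seed(seed)
  r0 <- abs(cor(x, y))
  hits <- sum(vapply(seq_len(n_perm), function(i) {
    abs(cor(x, sample(y))) >= r0
  }, logical(1)))
  (hits + 1) / (n_perm + 1)
}

# Trivariate normal sampler with a given correlation matrix (Cholesky).
rmvnorm3 <- function(n, R) {
  L <- chol(R)
  matrix(rnorm(n * 3), n, 3) %*% L
}

# Shared small fixtures --------------------------------------------------

# Deterministic mediation dataset (n = 20) with expected values frozen from
# an independent OLS implementation (statsmodels) at development time.
mediation_fixture <- function() {
  list(
    x = c(1.370958, -0.564698, 0.363128, 0.632863, 0.404268, -0.106125,
          1.511522, -0.094659, 2.018424, -0.062714, 1.30487, 2.286645,
          -1.388861, -0.278789, -0.133321, 0.63595, -0.284253, -2.656455,
          -2.440467, 1.320113),
    m = c(0.806351, -1.285943, 0.168231, 1.050341, 1.230584, -0.289522,
          0.929431, -0.947843, 1.642945, -0.363897, 1.141134, 1.95307,
          -0.454651, -0.499615, 0.159153, -0.413339, -0.591207, -2.284972,
          -2.915431, 0.94214),
    y = c(-0.380811, 0.591037, 0.278143, -0.993557, -1.422491, 0.390122,
          -0.963355, 1.290756, -1.20149, 0.546162, -0.523718, -1.563761,
          1.060654, 0.621219, -0.050611, 0.386279, 0.694369, 1.4159,
          0.252714, -0.422843),
    expected = list(a = 0.8846914417410991, b = -0.5762081932595525,
                    c_prime = -0.004189336247620037,
                    c_total = -0.5139557934854476,
                    sobel_z = -2.2581704949462216,
                    sobel_p = 0.023935031989631362)
  )
}

# Deterministic 16 x 2 reproducibility table with ICC(A,1) frozen from
# pingouin.intraclass_corr at development time.
icc_fixture <- function() {
  list(
    tab = matrix(c(-0.886128, 1.747426, -0.70326, -1.066658, -1.885821,
                   0.731305, 0.190641, -0.779485, -0.619086, 0.294322,
                   -0.877272, -1.228321, -0.706667, 0.192984, 0.184574,
                   0.332554, -1.751082, 1.041923, -1.142973, -1.162576,
                   -1.86025, -0.512052, 0.083704, -1.130481, -0.053972,
                   -0.149982, -0.488652, -2.091695, -0.933818, 0.236685,
                   -0.640943, -0.608465), 16, 2),
    expected_icc = 0.7624948735374993,
    expected_ci_2dp = c(0.30, 0.92)
  )
}

# Brute-force logistic psychometric fit: dense grid over (mu, slope),
# unweighted least squares on proportions.
oracle_grid_logistic <- function(isi, p, mu_range = c(-60, 60),
                                 slope_range = c(5, 150),
                                 mu_step = 0.5, slope_step = 0.25) {
  mus <- seq(mu_range[1], mu_range[2], by = mu_step)
  slopes <- seq(slope_range[1], slope_range[2], by = slope_step)
  best <- list(rss = Inf)
  for (s in slopes) {
    fitted <- plogis(outer(isi, mus, "-") / s)     # points x mus
    rss <- colSums((p - fitted)^2)
    j <- which.min(rss)
    if (rss[j] < best$rss) best <- list(rss = rss[j], mu = mus[j], slope = s)
  }
  best
}
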