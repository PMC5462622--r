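#' Pearson correlation with a two-tailed p value
#'
#' Standard Pearson r with significance from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-tailed. `pearson_p` computes the p value directly from a printed
#' (r, n) pair without raw data.
#'
#' @param x,y numeric vectors of equal length (n >= 4), finite, non-constant.
#' @return An object of class `correlation_result`: `r`, `n`,
#'   `p_two_tailed`, `fisher_z` (`atanh(r)`), `df`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input: correlation undefined")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  structure(list(r = r, n = n, p_two_tailed = pearson_p(r, n),
                 fisher_z = atanh(r), df = n - 2L),
            class = "correlation_result")
}

#' @rdname pearson_with_p
#' @param r Pearson coefficient.
#' @param n sample size.
#' @export
pearson_p <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 4)
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Compare two dependent overlapping correlations (Hittner's test)
#'
#' Tests whether `cor(x, y)` differs from `cor(x, z)` when both share the
#' variable x, using the back-transformed-average-z modification of the
#' Dunn and Clark statistic (Hittner, May and Silver): the two correlations
#' are Fisher transformed, their average z is back-transformed to a common
#' correlation used in the Dunn-Clark covariance term, and
#' `Z = (z_xy - z_xz) * sqrt((n - 3) / (2 - 2 * cov))` is referred to the
#' standard normal. Both one- and two-tailed p values are returned: printed
#' values in the source literature for this design match the one-tailed
#' normal tail despite blanket two-tailed statements, so neither convention
#' is hidden.
#'
#' @param r_xy,r_xz the two overlapping correlations (sharing x).
#' @param r_yz correlation between the non-shared variables.
#' @param n sample size (>= 10).
#' @return An object of class `dependent_corr_comparison`: inputs, `z_stat`,
#'   `p_one_tailed`, `p_two_tailed`.
#' @export
hittner_test <- function(r_xy, r_xz, r_yz, n) {
  stopifnot(n >= 10, abs(r_xy) < 1, abs(r_xz) < 1, abs(r_yz) <= 1)
  R <- matrix(c(1, r_xy, r_xz,
                r_xy, 1, r_yz,
                r_xz, r_yz, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("correlation triple is not positive semidefinite")
  }
  z1 <- atanh(r_xy)
  z2 <- atanh(r_xz)
  rm <- tanh((z1 + z2) / 2)                     # back-transformed average
  covterm <- (r_yz * (1 - 2 * rm^2) -
                0.5 * rm^2 * (1 - 2 * rm^2 - r_yz^2)) / (1 - rm^2)^2
  z_stat <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * covterm))
  structure(list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz, n = n,
                 z_stat = z_stat,
                 p_one_tailed = stats::pnorm(-abs(z_stat)),
                 p_two_tailed = 2 * stats::pnorm(-abs(z_stat))),
            class = "dependent_corr_comparison")
}

#' First-order partial correlation
#'
#' Correlation between x and y with a single covariate partialled out of
#' both, `(r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) (1 - r_yc^2))`, with the
#' two-tailed p value on `n - 3` degrees of freedom. Identical to
#' correlating the residuals of `x ~ covariate` and `y ~ covariate`.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector to partial out (not collinear with x or y).
#' @return a `correlation_result` (with `df = n - 3`).
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  stopifnot(length(y) == n, length(covariate) == n, n >= 5)
  if (stats::sd(covariate) == 0) stop("covariate has zero variance")
  rxy <- stats::cor(x, y); rxc <- stats::cor(x, covariate)
  ryc <- stats::cor(y, covariate)
  if (abs(rxc) >= 1 - 1e-12) {
    stop("covariate is collinear with x or y")
  }
  r <- if (abs(ryc) >= 1 - 1e-12) {
    0   # y is the covariate (up to affine): nothing left to correlate
  } else {
    (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
  }
  df <- n - 3L
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df = df)
  structure(list(r = r, n = n, p_two_tailed = p, fisher_z = atanh(r),
                 df = df),
            class = "correlation_result")
}

#' Conjunction / omnibus compound test over predicted and unpredicted p values
#'
#' The compound null is rejected only when every predicted correlation is
#' significant (conjunction statistic: the maximum predicted p) and no
#' unpredicted correlation is significant (omnibus statistic: the minimum
#' unpredicted p). This guards a directional hypothesis against both a
#' failed prediction and an unexpected off-target association.
#'
#' @param predicted_ps p values of the predicted (hypothesized) correlations.
#' @param unpredicted_ps p values of the unpredicted (control) correlations.
#' @param alpha significance level.
#' @return list with `conjunction_statistic` (max predicted p),
#'   `omnibus_statistic` (min unpredicted p), `reject` (logical verdict) and
#'   `alpha`.
#' @export
conjunction_omnibus <- function(predicted_ps, unpredicted_ps, alpha = 0.05) {
  stopifnot(length(predicted_ps) >= 1, length(unpredicted_ps) >= 1)
  ok <- function(p) all(p > 0 & p <= 1)
  if (!ok(predicted_ps) || !ok(unpredicted_ps)) {
    stop("p values must lie in (0, 1]")
  }
  conj <- max(predicted_ps)
  omni <- min(unpredicted_ps)
  list(conjunction_statistic = conj, omnibus_statistic = omni,
       reject = conj < alpha && omni >= alpha, alpha = alpha)
}

#' Normal-theory p values from printed Z statistics
#'
#' Utilities for recomputing significance from reported test statistics:
#' the Sobel Z of a mediation analysis is referred to the standard normal
#' two-tailed; the Hittner Z of a dependent-correlation comparison is
#' reported with both tail conventions (published values in this design
#' frequently correspond to the one-tailed normal tail).
#'
#' @param z the Z statistic.
#' @return p value(s).
#' @export
p_from_sobel_z <- function(z) 2 * stats::pnorm(-abs(z))

#' @rdname p_from_sobel_z
#' @param tails `"one"` or `"two"`.
#' @export
p_from_hittner_z <- function(z, tails = c("one", "two")) {
  tails <- match.arg(tails)
  p1 <- stats::pnorm(-abs(z))
  if (tails == "one") p1 else 2 * p1
}

# Preacher-Kelley kappa-squared: the indirect effect a*b relative to its
# maximum attainable magnitude given the observed variances and the
# positive-semidefiniteness of the covariance matrix of (x, m, y).
kappa_squared <- function(x, m, y) {
  S <- stats::cov(cbind(x, m, y))
  sxx <- S[1, 1]; smm <- S[2, 2]; syy <- S[3, 3]
  sxm <- S[1, 2]; sxy <- S[1, 3]; smy <- S[2, 3]
  a <- sxm / sxx
  b <- (smy * sxx - sxm * sxy) / (smm * sxx - sxm^2)
  disc_b <- (syy * sxx - sxy^2) / (smm * sxx - sxm^2)
  b_max <- sign(b) * sqrt(max(disc_b, 0))
  disc_a <- (sxx * syy - sxy^2) * (smm * syy - smy^2)
  half <- sqrt(max(disc_a, 0)) / syy
  ctr <- sxy * smy / syy
  sxm_max <- if (a >= 0) ctr + half else ctr - half
  a_max <- sxm_max / sxx
  denom <- a_max * b_max
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  min(max(abs(a * b) / abs(denom), 0), 1)
}

#' Simple mediation analysis with percentile bootstrap
#'
#' Decomposes the effect of x on y through a single mediator m using three
#' ordinary least-squares regressions: `m ~ x` gives the a path, `y ~ x + m`
#' gives the b path and the direct effect c', and `y ~ x` gives the total
#' effect c. The indirect effect is `a * b`, with a percentile confidence
#' interval from case-resampling bootstrap, the proportion mediated
#' `P_M = indirect / c_total`, the Sobel test
#' `Z = a*b / sqrt(b^2 SE_a^2 + a^2 SE_b^2)` with a two-tailed normal p,
#' and the Preacher-Kelley kappa-squared effect size (the indirect effect
#' relative to its maximum attainable magnitude given the observed
#' variances and correlations).
#'
#' @param x,m,y numeric vectors (n >= 10), e.g. GABA:Cr, cortical tuning,
#'   JND.
#' @param n_boot bootstrap resamples (>= 1000; 5000 by default).
#' @param seed integer seed; results are bit-reproducible given seed and
#'   `n_boot`.
#' @param conf confidence level of the percentile interval.
#' @return An object of class `mediation_result` with fields `a`, `b`,
#'   `c_total`, `c_prime`, `indirect`, `boot_ci`, `p_m`, `p_m_unstable`
#'   (TRUE when `|c_total|` is small relative to its SE, making the ratio
#'   unreliable), `sobel_z`, `sobel_p`, `kappa2`, `n`, `n_boot`, `seed`.
#' @export
mediate <- function(x, m, y, n_boot = 5000, seed = 1, conf = 0.95) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, n >= 10, n_boot >= 1000)
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("zero variance input")
  }
  paths <- function(xi, mi, yi) {
    fa <- stats::lm(mi ~ xi)
    fb <- stats::lm(yi ~ xi + mi)
    fc <- stats::lm(yi ~ xi)
    c(a = unname(stats::coef(fa)[2]), b = unname(stats::coef(fb)[3]),
      c_prime = unname(stats::coef(fb)[2]), c_total = unname(stats::coef(fc)[2]),
      se_a = unname(sqrt(diag(stats::vcov(fa))[2])),
      se_b = unname(sqrt(diag(stats::vcov(fb))[3])),
      se_c = unname(sqrt(diag(stats::vcov(fc))[2])))
  }
  p0 <- paths(x, m, y)
  indirect <- p0[["a"]] * p0[["b"]]

  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; mb <- m[idx]; yb <- y[idx]
    am <- stats::coef(stats::lm(mb ~ xb))[2]
    bm <- stats::coef(stats::lm(yb ~ xb + mb))[3]
    unname(am * bm)
  }, numeric(1))
  alpha2 <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha2, 1 - alpha2), type = 6))

  sobel_z <- indirect / sqrt(p0[["b"]]^2 * p0[["se_a"]]^2 +
                               p0[["a"]]^2 * p0[["se_b"]]^2)
  p_m <- indirect / p0[["c_total"]]
  structure(list(
    a = p0[["a"]], b = p0[["b"]], c_total = p0[["c_total"]],
    c_prime = p0[["c_prime"]], indirect = indirect,
    boot_ci = ci, conf = conf,
    p_m = p_m,
    p_m_unstable = abs(p0[["c_total"]]) < 2 * p0[["se_c"]],
    sobel_z = sobel_z, sobel_p = 2 * stats::pnorm(-abs(sobel_z)),
    kappa2 = kappa_squared(x, m, y),
    n = n, n_boot = n_boot, seed = seed
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (n = %d): a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n",
              x$n, x$a, x$b, x$c_total, x$c_prime))
  cat(sprintf("  indirect = %.3f, %d%% bootstrap CI [%.3f, %.3f] (%d resamples)\n",
              x$indirect, round(100 * x$conf), x$boot_ci[1], x$boot_ci[2],
              x$n_boot))
  cat(sprintf("  P_M = %.2f%s, Sobel Z = %.2f (p = %.4f), kappa2 = %.4f\n",
              x$p_m, if (isTRUE(x$p_m_unstable)) " [unstable]" else "",
              x$sobel_z, x$sobel_p, x$kappa2))
  invisible(x)
}

#' Single-measures intraclass correlation, two-way random, absolute agreement
#'
#' ICC(A,1) in the McGraw-Wong scheme (equivalently ICC(2,1) of Shrout and
#' Fleiss): from the two-way ANOVA decomposition of a complete subjects x
#' sessions table,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the F-based 95% confidence interval of McGraw and Wong. Absolute
#' agreement penalizes systematic session differences (adding a constant to
#' one session lowers the ICC), unlike the consistency form.
#'
#' @param measurements numeric matrix or data frame, subjects in rows,
#'   sessions in columns; complete, >= 5 subjects, >= 2 sessions.
#' @param conf confidence level.
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_sessions`, mean squares.
#' @export
icc_a1 <- function(measurements, conf = 0.95) {
  x <- as.matrix(measurements)
  if (anyNA(x)) stop("incomplete table: ICC requires complete data")
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 5, k >= 2)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf
  if (mse == 0 && msc == 0) {
    lo <- hi <- 1
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 n_subjects = n, n_sessions = k,
                 msr = msr, msc = msc, mse = mse, conf = conf),
            class = "icc_result")
}
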