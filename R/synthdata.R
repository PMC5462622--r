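#' Ground-truth voxel grid for simulated digit-cycling runs
#'
#' Describes the true tuning of each voxel in a small simulated patch of
#' somatosensory cortex: a preferred digit, a tuning width (spread of the
#' response over circular digit distance), a signal amplitude and a noise
#' model (Gaussian, optionally AR(1)).
#'
#' @param shape voxel-grid dimensions, length 3.
#' @param preferred_digit per-voxel preferred digit, values drawn from
#'   `digits`; recycled to the grid size. Default assigns digits in
#'   stripes, mimicking a somatotopic gradient.
#' @param tuning_width per-voxel positive tuning width (dimensionless,
#'   in units of circular digit distance); recycled.
#' @param amplitude per-voxel signal gain; recycled.
#' @param noise_sd per-voxel noise SD; recycled.
#' @param noise_ar1 lag-1 noise autocorrelation in `[0, 1)`.
#' @param digits digit labels the grid is tuned over.
#' @return object of class `sim_grid`.
#' @export
sim_grid <- function(shape = c(4, 4, 1), preferred_digit = NULL,
                     tuning_width = 0.8, amplitude = 1, noise_sd = 0.5,
                     noise_ar1 = 0, digits = 2:5) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  nvox <- prod(shape)
  if (is.null(preferred_digit)) {
    preferred_digit <- digits[((seq_len(nvox) - 1) %% length(digits)) + 1]
  }
  preferred_digit <- rep_len(preferred_digit, nvox)
  tuning_width <- rep_len(tuning_width, nvox)
  amplitude <- rep_len(amplitude, nvox)
  noise_sd <- rep_len(noise_sd, nvox)
  stopifnot(all(preferred_digit %in% digits), all(tuning_width > 0),
            all(noise_sd >= 0), noise_ar1 >= 0, noise_ar1 < 1)
  structure(list(shape = as.integer(shape), preferred_digit = preferred_digit,
                 tuning_width = tuning_width, amplitude = amplitude,
                 noise_sd = noise_sd, noise_ar1 = noise_ar1, digits = digits),
            class = "sim_grid")
}

# Wrapped-Gaussian tuning weight over circular digit distance.
# delta: signed digit-index distance; n: number of digits in the cycle.
wrapped_gaussian_weight <- function(delta, width, n) {
  k <- -2:2
  vapply(delta, function(d) sum(exp(-(d + k * n)^2 / (2 * width^2))), numeric(1))
}

#' Simulate one digit-cycling fMRI run
#'
#' Each voxel's noiseless signal is a weighted sum of the HRF-convolved
#' block regressors of the digits, the weights following a wrapped-Gaussian
#' tuning function of circular digit distance from the voxel's preferred
#' digit (normalized to peak 1 so that as width shrinks the signal converges
#' to the preferred digit's lag-shifted reference model exactly). Gaussian
#' noise with optional AR(1) structure is added with the stated marginal SD.
#'
#' @param grid a [sim_grid()].
#' @param design a [task_design()]; its `digits` must match the grid's. The
#'   design's `direction` controls forward/backward cycling ("backward"
#'   reverses the digit order within the cycle).
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @return list with `img` (4D array x,y,z,t), `cues` (data frame of block
#'   onsets: `onset_s`, `digit`), `press_cues` (1 Hz press cue times within
#'   blocks) and `truth` (the grid).
#' @examples
#' run <- simulate_fmri_run(sim_grid(c(2, 2, 1)), task_design(), seed = 1)
#' dim(run$img)
#' @export
simulate_fmri_run <- function(grid, design, seed = 1) {
  stopifnot(inherits(grid, "sim_grid"), inherits(design, "task_design"))
  if (!identical(as.integer(grid$digits), as.integer(design$digits))) {
    stop("grid and design digit sets differ")
  }
  order_d <- digit_cycle_order(design)
  nd <- length(order_d)
  # lag of each digit's block within the cycle, by cued order
  lag_of <- stats::setNames((match(grid$digits, order_d) - 1) * design$block_s,
                            grid$digits)
  regs <- vapply(grid$digits, function(d)
    build_reference_model(design, lag_of[[as.character(d)]]),
    numeric(design$n_volumes))                 # T x nd
  nvox <- prod(grid$shape)
  nt <- design$n_volumes

  # tuning weights: voxels x digits, peak-normalized
  pos <- match(grid$preferred_digit, grid$digits)
  W <- matrix(0, nvox, nd)
  for (v in seq_len(nvox)) {
    w <- wrapped_gaussian_weight(seq_len(nd) - pos[v], grid$tuning_width[v], nd)
    W[v, ] <- w / max(w)
  }
  signal <- (W %*% t(regs)) * grid$amplitude   # voxels x time

  set.seed(seed)
  noise <- matrix(stats::rnorm(nvox * nt), nvox, nt)
  if (grid$noise_ar1 > 0) {
    rho <- grid$noise_ar1
    for (t in 2:nt) noise[, t] <- rho * noise[, t - 1] + sqrt(1 - rho^2) * noise[, t]
  }
  noise <- noise * grid$noise_sd
  img <- array(as.numeric(signal + noise), c(grid$shape, nt))

  onsets <- (seq_len(design$n_cycles * nd) - 1) * design$block_s
  cues <- data.frame(onset_s = onsets,
                     digit = rep(order_d, design$n_cycles))
  press_cues <- as.numeric(outer(0:(design$block_s - 1), onsets, "+"))
  list(img = img, cues = cues, press_cues = sort(press_cues), truth = grid)
}

#' Ideal temporal-order-judgment observer
#'
#' A logistic observer for the two-finger vibrotactile temporal order
#' judgment: the probability of judging "middle finger first" at
#' interstimulus interval ISI (positive = middle finger actually first) is
#' `lapse/2 + (1 - lapse) / (1 + exp(-(ISI - mu)/slope))`. A lapse-free
#' observer has true JND `slope * log(3)`.
#'
#' @param mu bias (point of subjective simultaneity), ms.
#' @param slope logistic scale, ms (> 0).
#' @param lapse symmetric lapse rate in `[0, 0.1]`.
#' @return object of class `toj_observer`.
#' @export
toj_observer <- function(mu = 0, slope = 50, lapse = 0) {
  if (slope <= 0) stop("slope must be positive")
  stopifnot(lapse >= 0, lapse <= 0.1)
  structure(list(mu = mu, slope = slope, lapse = lapse), class = "toj_observer")
}

#' Response probability of a TOJ observer
#' @param observer a [toj_observer()].
#' @param isi interstimulus interval(s), ms.
#' @return probability of a "middle-first" response.
#' @export
toj_prob <- function(observer, isi) {
  p <- stats::plogis((isi - observer$mu) / observer$slope)
  observer$lapse / 2 + (1 - observer$lapse) * p
}

#' Simulate temporal-order-judgment trials
#'
#' Draws Bernoulli responses from a logistic observer at each interstimulus
#' interval. The default ISI set is the standard 12-level design
#' (+/- 350, 250, 150, 100, 60, 30 ms) with 16 trials per ISI (192 trials).
#'
#' @param observer a [toj_observer()].
#' @param isis ISIs in ms (positive = middle finger stimulated first).
#' @param trials_per_isi trials at each ISI (>= 1).
#' @param seed integer seed.
#' @return data frame with columns `isi_ms` and `response`
#'   (`"middle_first"` / `"index_first"`), `length(isis) * trials_per_isi`
#'   rows.
#' @export
simulate_toj_trials <- function(observer,
                                isis = c(-350, -250, -150, -100, -60, -30,
                                         30, 60, 100, 150, 250, 350),
                                trials_per_isi = 16, seed = 1) {
  stopifnot(inherits(observer, "toj_observer"), length(isis) >= 1,
            trials_per_isi >= 1)
  set.seed(seed)
  isi_col <- rep(isis, each = trials_per_isi)
  p <- toj_prob(observer, isi_col)
  resp <- ifelse(stats::runif(length(p)) < p, "middle_first", "index_first")
  data.frame(isi_ms = isi_col, response = resp)
}

#' Ground truth for a simulated cohort under a mediation structure
#'
#' Structural equations for the three per-subject variables: neurochemistry
#' X (GABA:Cr), cortical tuning M, perceptual acuity Y (JND):
#' `M = a*X + e_M`, `Y = c'*X + b*M + e_Y` with `X ~ N(0, 1)` and Gaussian
#' residuals. These latent variables are mapped affinely onto realistic
#' measurement scales (which leaves every correlation-based statistic
#' unchanged).
#'
#' @param n_subjects cohort size (>= 4).
#' @param path_a effect of X on M.
#' @param path_b effect of M on Y.
#' @param path_c_prime direct effect of X on Y.
#' @param noise_sd_m,noise_sd_y residual SDs.
#' @return object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_subjects = 22, path_a = 0.7, path_b = -0.6,
                         path_c_prime = 0, noise_sd_m = 0.5, noise_sd_y = 0.5) {
  stopifnot(n_subjects >= 4, noise_sd_m >= 0, noise_sd_y >= 0)
  structure(list(n_subjects = n_subjects, path_a = path_a, path_b = path_b,
                 path_c_prime = path_c_prime, noise_sd_m = noise_sd_m,
                 noise_sd_y = noise_sd_y), class = "cohort_truth")
}

#' Covariance of (X, M, Y) implied by the structural equations
#'
#' Closed-form implied covariance used as an oracle for the generator:
#' with X ~ N(0,1), `Var(M) = a^2 + s_m^2`,
#' `Cov(X, Y) = c' + a*b`, etc.
#'
#' @param truth a [cohort_truth()].
#' @return 3x3 covariance matrix with dimnames X, M, Y.
#' @export
implied_covariance <- function(truth) {
  a <- truth$path_a; b <- truth$path_b; cp <- truth$path_c_prime
  vm <- a^2 + truth$noise_sd_m^2
  cxm <- a
  cxy <- cp + a * b
  cmy <- a * cp + b * vm
  vy <- cp^2 + b^2 * vm + 2 * cp * b * a + truth$noise_sd_y^2
  m <- matrix(c(1, cxm, cxy,
                cxm, vm, cmy,
                cxy, cmy, vy), 3, 3,
              dimnames = list(c("X", "M", "Y"), c("X", "M", "Y")))
  m
}

# Affine maps from latent (X, M, Y) to measurement scales. Chosen once to
# land in the ranges typical of 7T MRS GABA:Cr ratios, 1/period tuning
# metrics and TOJ JNDs; correlations are unaffected.
latent_to_metrics <- function(X, M, Y) {
  data.frame(
    gaba_cr = 0.25 + 0.04 * X,
    tuning = 0.060 + 0.010 * M,
    jnd = 90 + 25 * Y
  )
}

#' Simulate a cohort of per-subject metrics under known mediation truth
#'
#' Metric-level mode draws (X, M, Y) from the structural equations and maps
#' them to measurement scales. Raw-level mode additionally attaches, per
#' subject, the generative parameters from which the raw data streams can
#' be simulated: the subject's true tuning is mapped monotonically to a
#' voxel tuning width (sharper tuning, smaller width) and the true JND to a
#' logistic observer slope (`slope = jnd / log(3)`).
#'
#' @param truth a [cohort_truth()].
#' @param seed integer seed.
#' @param raw_level if TRUE, include `tuning_width` and `toj_slope` columns
#'   linking each subject to raw-data generators.
#' @return data frame with columns `subject`, `gaba_cr`, `tuning`, `jnd`
#'   (plus latent `X`, `M`, `Y`, and raw-level link columns if requested).
#' @export
simulate_cohort <- function(truth, seed = 1, raw_level = FALSE) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(seed)
  n <- truth$n_subjects
  X <- stats::rnorm(n)
  M <- truth$path_a * X + stats::rnorm(n, sd = truth$noise_sd_m)
  Y <- truth$path_c_prime * X + truth$path_b * M +
    stats::rnorm(n, sd = truth$noise_sd_y)
  out <- cbind(data.frame(subject = sprintf("S%02d", seq_len(n))),
               latent_to_metrics(X, M, Y),
               data.frame(X = X, M = M, Y = Y))
  if (raw_level) {
    # monotone links, calibrated once by simulation: higher tuning metric
    # maps to a sharper (smaller) wrapped-Gaussian width, with a cubic
    # steepening so the cohort spans the width range where the fitted
    # period is most sensitive (~0.4-1.6); larger JND maps to a shallower
    # observer slope (slope = jnd / ln 3 recovers the JND exactly).
    rel <- pmax(out$tuning, 0.02) / 0.060
    out$tuning_width <- pmin(2.5, pmax(0.25, 0.8 * rel^-3))
    out$toj_slope <- pmax(5, out$jnd) / log(3)
  }
  out
}

#' Simulate an MRS metabolite quantification table
#'
#' Emulates an LCModel-style output table for `n` spectra (one voxel
#' acquisition per subject), each contributing GABA, Glu, Cr and PCr rows
#' that share the spectrum-level quality fields (water linewidth, SNR) and
#' tissue fractions (GM/WM/CSF summing to 1). A stated fraction of spectra
#' are made to violate at least one quality rule (CRLB > 50 on GABA,
#' FWHM > 15 Hz, or SNR < 40), chosen at random.
#'
#' @param n number of spectra (subjects).
#' @param qc_fail_fraction fraction of spectra forced to fail QC, in `[0, 1]`;
#'   exactly `round(n * qc_fail_fraction)` spectra fail.
#' @param seed integer seed.
#' @param gaba_mean,glu_mean,cr_mean,pcr_mean mean absolute concentrations
#'   (institutional units).
#' @return data frame with columns `subject`, `metabolite`, `absolute`,
#'   `crlb`, `fwhm_hz`, `snr`, `gm`, `wm`, `csf`; `4 * n` rows.
#' @export
simulate_mrs_table <- function(n, qc_fail_fraction = 0, seed = 1,
                               gaba_mean = 1.5, glu_mean = 9,
                               cr_mean = 4.5, pcr_mean = 3.5) {
  stopifnot(qc_fail_fraction >= 0, qc_fail_fraction <= 1, n >= 1)
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(n))
  # passing-spectrum QC values, comfortably inside the rules
  fwhm <- stats::runif(n, 7, 11)
  snr <- stats::runif(n, 55, 90)
  gm <- stats::runif(n, 0.35, 0.55)
  wm <- stats::runif(n, 0.30, 0.50)
  csf <- pmax(0, 1 - gm - wm)
  tot <- gm + wm + csf
  gm <- gm / tot; wm <- wm / tot; csf <- csf / tot

  means <- c(GABA = gaba_mean, Glu = glu_mean, Cr = cr_mean, PCr = pcr_mean)
  crlb_pass <- c(GABA = 12, Glu = 4, Cr = 2, PCr = 3)
  n_fail <- round(n * qc_fail_fraction)
  fail_idx <- if (n_fail > 0) sample(n, n_fail) else integer(0)
  fail_rule <- sample(c("crlb", "fwhm", "snr"), n_fail, replace = TRUE)
  gaba_crlb <- rep(crlb_pass[["GABA"]], n)
  for (k in seq_along(fail_idx)) {
    i <- fail_idx[k]
    switch(fail_rule[k],
           crlb = { gaba_crlb[i] <- stats::runif(1, 55, 90) },
           fwhm = { fwhm[i] <- stats::runif(1, 16, 25) },
           snr  = { snr[i] <- stats::runif(1, 15, 38) })
  }
  rows <- lapply(names(means), function(met) {
    data.frame(
      subject = subj, metabolite = met,
      absolute = pmax(0.05, stats::rnorm(n, means[[met]], 0.1 * means[[met]])),
      crlb = if (met == "GABA") gaba_crlb else rep(crlb_pass[[met]], n),
      fwhm_hz = fwhm, snr = snr, gm = gm, wm = wm, csf = csf)
  })
  out <- do.call(rbind, rows)
  out[order(out$subject, out$metabolite), , drop = FALSE]
}
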