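#' Describe the timing of a digit-cycling fMRI task
#'
#' The traveling-wave paradigm moves a block of activity continuously through
#' the digits: each digit is cued for `block_s` seconds, the full cycle over
#' all digits lasts `cycle_s = length(digits) * block_s` seconds, and the
#' cycle repeats `n_cycles` times with no rest. The default reproduces the
#' standard hand protocol: digits 2-5 (index to little finger), 8 s blocks,
#' 32 s cycle repeated 8 times, sampled at TR = 1.5 s. A backward run cycles
#' through the digits in reverse order (little finger to index).
#'
#' @param tr sampling interval of the scanner, seconds.
#' @param block_s duration of one digit's movement block, seconds.
#' @param n_cycles number of repetitions of the full cycle.
#' @param digits ordered digit labels (forward order).
#' @param direction `"forward"` or `"backward"`.
#' @return An object of class `task_design` with fields `tr`, `block_s`,
#'   `cycle_s`, `n_cycles`, `digits`, `direction`, `run_s` (total duration)
#'   and `n_volumes` (volumes acquired, `floor(run_s / tr)`).
#' @examples
#' d <- task_design()
#' d$cycle_s     # 32
#' d$n_volumes   # 170
#' @export
task_design <- function(tr = 1.5, block_s = 8, n_cycles = 8,
                        digits = 2:5, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(tr > 0, block_s > 0, n_cycles >= 1, length(digits) >= 2)
  cycle_s <- length(digits) * block_s
  run_s <- n_cycles * cycle_s
  structure(list(
    tr = tr, block_s = block_s, cycle_s = cycle_s, n_cycles = n_cycles,
    digits = digits, direction = direction, run_s = run_s,
    n_volumes = as.integer(floor(run_s / tr + 1e-9))
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "task_design: %d digits (%s, %s), %g s blocks, %g s cycle x %d, TR %g s, %d volumes\n",
    length(x$digits), paste(x$digits, collapse = ","), x$direction,
    x$block_s, x$cycle_s, x$n_cycles, x$tr, x$n_volumes))
  invisible(x)
}

#' Order in which digits are cued within a cycle
#'
#' @param design a [task_design()].
#' @return digit labels in cued order (reversed for backward runs).
#' @export
digit_cycle_order <- function(design) {
  if (design$direction == "backward") rev(design$digits) else design$digits
}

#' Gamma hemodynamic response function
#'
#' Gamma-density HRF used to convolve block regressors. The default (shape 6,
#' scale 0.9 s, no undershoot) peaks around 4.5 s, the conventional
#' single-gamma shape for block designs.
#'
#' @param t time grid, seconds.
#' @param shape,scale gamma parameters (scale in seconds).
#' @return HRF values on `t`, scaled to unit peak.
#' @export
hrf_gamma <- function(t, shape = 6, scale = 0.9) {
  h <- stats::dgamma(t, shape = shape, scale = scale)
  if (max(h) > 0) h <- h / max(h)
  h
}

# Periodic boxcar for one digit block, HRF-convolved and sampled at TR.
# Internal workhorse shared by build_reference_model and the simulator.
# Convolution is effectively circular: one extra leading cycle is prepended
# (the task runs continuously, so the run starts in steady state) and then
# discarded.
convolved_block_regressor <- function(design, lag, dt = 0.1,
                                      hrf_shape = 6, hrf_scale = 0.9) {
  if (lag < 0 || lag >= design$cycle_s) {
    stop("lag must lie in [0, cycle_s): got ", lag)
  }
  cyc_n <- round(design$cycle_s / dt)
  one_cycle <- as.numeric(seq_len(cyc_n) <= round(design$block_s / dt))
  shift <- round(lag / dt) %% cyc_n
  if (shift > 0) {
    one_cycle <- c(one_cycle[(cyc_n - shift + 1):cyc_n], one_cycle[1:(cyc_n - shift)])
  }
  box <- rep(one_cycle, design$n_cycles + 1)  # +1 leading cycle for wrap-in
  h <- hrf_gamma(seq(0, 32, by = dt), shape = hrf_shape, scale = hrf_scale)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(box)] * dt
  conv <- conv[-seq_len(cyc_n)]               # drop the wrap-in cycle
  fine_t <- (seq_along(conv) - 1) * dt
  samp_t <- (seq_len(design$n_volumes) - 1) * design$tr
  idx <- round(samp_t / dt) + 1
  conv[pmin(idx, length(conv))]
}

#' Lag-shifted reference model for traveling-wave cross-correlation
#'
#' Builds the single-digit block regressor: a boxcar that is on for
#' `block_s` seconds and off for the rest of the cycle, repeated `n_cycles`
#' times, circularly shifted by `lag` seconds within the cycle, convolved
#' with a gamma HRF on a fine (0.1 s) grid and sampled at the TR. The result
#' is normalized to zero mean and unit variance so correlations against it
#' are well scaled.
#'
#' @param design a [task_design()].
#' @param lag circular shift in seconds, in `[0, cycle_s)`.
#' @param dt fine time grid step for convolution, seconds.
#' @param hrf_shape,hrf_scale gamma HRF parameters (see [hrf_gamma()]).
#' @return numeric vector of length `design$n_volumes`, zero mean, unit SD.
#' @examples
#' m0 <- build_reference_model(task_design(), lag = 0)
#' m8 <- build_reference_model(task_design(), lag = 8)
#' cor(m0, m8)
#' @export
build_reference_model <- function(design, lag, dt = 0.1,
                                  hrf_shape = 6, hrf_scale = 0.9) {
  y <- convolved_block_regressor(design, lag, dt = dt,
                                 hrf_shape = hrf_shape, hrf_scale = hrf_scale)
  as.numeric(scale(y))
}

#' Default lag grid spanning one cycle
#'
#' @param design a [task_design()].
#' @param step lag step in seconds; defaults to the TR.
#' @return strictly increasing lags in `[0, cycle_s)`.
#' @export
default_lag_grid <- function(design, step = design$tr) {
  lags <- seq(0, design$cycle_s - 1e-9, by = step)
  lags[lags < design$cycle_s]
}

#' Voxel tuning profile by cross-correlation against shifted models
#'
#' Correlates one voxel's time series against the reference model shifted to
#' every lag on the grid, yielding the tuning profile: correlation as a
#' function of position in the movement cycle. The profile peaks at the lag
#' where the voxel responds maximally, i.e. at its preferred digit's slot.
#'
#' @param ts numeric time series of length `design$n_volumes`.
#' @param design a [task_design()].
#' @param lag_grid lags in seconds within `[0, cycle_s)`; defaults to
#'   [default_lag_grid()].
#' @param models optional precomputed list of reference models (one per lag,
#'   as returned by [build_reference_model()]) to amortize across voxels.
#' @return An object of class `tuning_profile`: list with `lags`, `r`, and
#'   `ok` (FALSE for degenerate, e.g. constant, series whose correlation is
#'   undefined; such voxels are excluded downstream).
#' @export
compute_tuning_profile <- function(ts, design, lag_grid = default_lag_grid(design),
                                   models = NULL) {
  stopifnot(length(ts) == design$n_volumes)
  stopifnot(all(lag_grid >= 0), all(lag_grid < design$cycle_s),
            !is.unsorted(lag_grid, strictly = TRUE))
  if (is.null(models)) {
    models <- lapply(lag_grid, function(l) build_reference_model(design, l))
  }
  ok <- stats::sd(ts) > 0 && all(is.finite(ts))
  r <- if (ok) vapply(models, function(m) stats::cor(ts, m), numeric(1)) else
    rep(NA_real_, length(lag_grid))
  structure(list(lags = lag_grid, r = r, ok = ok, cycle_s = design$cycle_s),
            class = "tuning_profile")
}

# Profiled least squares for y = a*sin(w*x - phi) + B at fixed w:
# linear in (a*cos(phi), -a*sin(phi), B). Returns rss and parameters.
sin_fit_at_omega <- function(x, y, omega) {
  X <- cbind(sin(omega * x), cos(omega * x), 1)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  res <- y - X %*% cf
  a <- sqrt(cf[1]^2 + cf[2]^2)
  phi <- atan2(-cf[2], cf[1])
  list(rss = sum(res^2), a = a, phi = phi, B = cf[3])
}

#' Fit a sinusoid to a tuning profile
#'
#' Least-squares fit of `y = a * sin(omega * x - phi) + B` to the profile's
#' correlation values over the lag axis. For a fixed angular frequency the
#' model is linear in the remaining parameters, so the fit profiles them out
#' exactly and searches only over the period: a coarse grid over
#' `[2 * lag step, 2 * cycle_s]` followed by bounded 1-D refinement
#' ([stats::optimize()] on the bracketing interval). This computes the same
#' global least-squares estimate as a multi-start 4-parameter solver, more
#' robustly.
#'
#' The fitted period (in seconds of lag) measures the width of the voxel's
#' response during the movement cycle: sharper, more selective voxels have
#' shorter periods.
#'
#' The tuning profile is circular (lag 0 and lag `cycle_s` name the same
#' point of the cycle), but a sinusoid with a free period is not periodic in
#' the window. Fitting a profile whose peak happens to sit near the cut
#' point therefore splits the bump across the window edges and biases the
#' period upward. When the profile carries its cycle length (profiles from
#' [compute_tuning_profile()] do) and `recenter = TRUE` (the default), the
#' circular lag coordinate is re-cut so the peak lies at the center of the
#' axis — an exact re-parameterization, since the profile is by construction
#' periodic in the cycle — and the fitted phase is mapped back to the
#' original axis. Plain `lags`/`r` lists without a `cycle_s` field are
#' fitted as-is.
#'
#' @param profile a [compute_tuning_profile()] result, or any list with
#'   numeric `lags` and `r` of equal length (>= 8 points) and optionally
#'   `cycle_s`.
#' @param period_bounds optional length-2 bounds on the period, seconds;
#'   default `c(2 * lag step, 2 * span)` where span is the lag range.
#' @param n_grid size of the coarse period grid.
#' @param recenter recenter circular profiles on their peak (see above).
#' @return An object of class `sinusoid_fit`: `a` (>= 0), `omega`, `phi`,
#'   `B`, `period = 2*pi/omega`, `rss`, `r_squared`, `converged`, and
#'   `degenerate` (TRUE when the profile is essentially constant). `rss` is
#'   measured on the (possibly recentered) axis actually fitted.
#' @export
fit_sinusoid <- function(profile, period_bounds = NULL, n_grid = 60,
                         recenter = TRUE) {
  x <- profile$lags
  y <- profile$r
  shift_s <- 0
  cyc <- profile$cycle_s
  if (recenter && !is.null(cyc) && all(is.finite(y)) && length(y) >= 2) {
    delta <- x[which.max(y)] - cyc / 2
    x2 <- (x - delta) %% cyc
    ord <- order(x2)
    x <- x2[ord]
    y <- y[ord]
    shift_s <- delta
  }
  if (length(x) < 8) stop("need at least 8 lag points to fit a sinusoid")
  if (!all(is.finite(y))) {
    return(structure(list(a = NA_real_, omega = NA_real_, phi = NA_real_,
                          B = NA_real_, period = NA_real_, rss = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          degenerate = TRUE), class = "sinusoid_fit"))
  }
  step <- stats::median(diff(x))            # robust to the re-cut wrap gap
  span <- (max(x) - min(x)) + step          # one full cycle when grid spans it
  if (is.null(period_bounds)) period_bounds <- c(2 * step, 2 * span)
  degenerate <- stats::sd(y) < 1e-12

  periods <- exp(seq(log(period_bounds[1]), log(period_bounds[2]),
                     length.out = n_grid))
  omegas <- 2 * pi / periods
  rsss <- vapply(omegas, function(w) sin_fit_at_omega(x, y, w)$rss, numeric(1))
  i <- which.min(rsss)
  lo <- omegas[min(i + 1, length(omegas))]  # omegas decrease with period
  hi <- omegas[max(i - 1, 1)]
  opt <- stats::optimize(function(w) sin_fit_at_omega(x, y, w)$rss,
                         lower = min(lo, hi), upper = max(lo, hi),
                         tol = 1e-10)
  best_w <- if (opt$objective <= rsss[i]) opt$minimum else omegas[i]
  p <- sin_fit_at_omega(x, y, best_w)
  tss <- sum((y - mean(y))^2)
  # map phase back to the original (un-recentered) lag axis
  phi_out <- p$phi + best_w * shift_s
  phi_out <- atan2(sin(phi_out), cos(phi_out))
  p$phi <- phi_out
  structure(list(
    a = unname(p$a), omega = unname(best_w), phi = unname(p$phi),
    B = unname(p$B), period = unname(2 * pi / best_w), rss = unname(p$rss),
    r_squared = if (tss > 0) max(0, 1 - p$rss / tss) else NA_real_,
    converged = TRUE, degenerate = degenerate
  ), class = "sinusoid_fit")
}

#' Fit tuning maps for a whole run
#'
#' Applies [compute_tuning_profile()] and [fit_sinusoid()] to every voxel of
#' a 4D run, producing voxel-wise amplitude, period and phase maps.
#' Backward-run lag axes are re-indexed to the forward digit order (lag
#' `cycle_s - lag`, modulo the cycle) before fitting is *not* needed for the
#' amplitude/period maps (both are invariant to reversing the lag axis), so
#' maps from forward and backward runs are directly comparable.
#'
#' @param img 4D array (x, y, z, t).
#' @param design a [task_design()].
#' @param lag_grid lags in seconds; defaults to [default_lag_grid()].
#' @return An object of class `tuning_maps`: 3D arrays `amplitude`,
#'   `period`, `phase`, logical `converged`, plus `n_timepoints`,
#'   `n_lags` and the count of excluded (non-converged or degenerate)
#'   voxels `n_excluded`.
#' @export
fit_tuning_maps <- function(img, design, lag_grid = default_lag_grid(design)) {
  stopifnot(length(dim(img)) == 4, dim(img)[4] == design$n_volumes)
  shape <- dim(img)[1:3]
  models <- lapply(lag_grid, function(l) build_reference_model(design, l))
  nvox <- prod(shape)
  mat <- matrix(img, nrow = nvox)           # voxels x time
  amp <- per <- pha <- rep(NA_real_, nvox)
  conv <- rep(FALSE, nvox)
  for (v in seq_len(nvox)) {
    prof <- compute_tuning_profile(mat[v, ], design, lag_grid, models = models)
    if (!prof$ok) next
    f <- fit_sinusoid(prof)
    if (f$converged && !f$degenerate) {
      amp[v] <- f$a; per[v] <- f$period; pha[v] <- f$phi
      conv[v] <- TRUE
    }
  }
  structure(list(
    amplitude = array(amp, shape), period = array(per, shape),
    phase = array(pha, shape), converged = array(conv, shape),
    n_timepoints = design$n_volumes, n_lags = length(lag_grid),
    n_excluded = sum(!conv)
  ), class = "tuning_maps")
}

#' Average tuning maps across forward and backward runs
#'
#' Voxel-wise arithmetic mean of the amplitude and period maps from the two
#' task variants. Only voxels with converged fits in both runs contribute;
#' all others are NA and excluded from the region of interest.
#'
#' @param forward,backward `tuning_maps` of identical spatial shape.
#' @return a combined `tuning_maps` object.
#' @export
combine_runs <- function(forward, backward) {
  stopifnot(inherits(forward, "tuning_maps"), inherits(backward, "tuning_maps"))
  if (!identical(dim(forward$amplitude), dim(backward$amplitude))) {
    stop("forward and backward maps have different spatial shapes")
  }
  both <- forward$converged & backward$converged
  amp <- (forward$amplitude + backward$amplitude) / 2
  per <- (forward$period + backward$period) / 2
  amp[!both] <- NA_real_
  per[!both] <- NA_real_
  structure(list(
    amplitude = amp, period = per, phase = forward$phase,
    converged = both,
    n_timepoints = forward$n_timepoints, n_lags = forward$n_lags,
    n_excluded = sum(!both)
  ), class = "tuning_maps")
}

#' FDR-thresholded region of interest from an amplitude map
#'
#' The amplitude of the fitted sinusoid lives on the correlation scale, so
#' each voxel's amplitude is Fisher r-to-Z transformed
#' (`z = atanh(r) * sqrt(n - 3)`), converted to a two-sided normal p value,
#' and the map is thresholded by Benjamini-Hochberg false-discovery-rate
#' control at level `alpha` (default 0.01). Surviving voxels form the ROI
#' over which the tuning metric is averaged.
#'
#' @param amplitude_map 3D array of r-scale amplitudes in `[0, 1)`; NA
#'   voxels (non-converged fits) are never selected.
#' @param n_timepoints time points behind each correlation (> 3).
#' @param alpha FDR level in (0, 1).
#' @return An object of class `roi_mask`: logical `mask` array, `alpha`,
#'   `n_voxels` selected, and `p_adjusted` map.
#' @export
define_roi <- function(amplitude_map, n_timepoints, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1, n_timepoints > 3)
  r <- as.numeric(amplitude_map)
  if (any(r >= 1 | r < 0, na.rm = TRUE)) {
    stop("amplitudes must lie in [0, 1) on the correlation scale")
  }
  z <- atanh(r) * sqrt(n_timepoints - 3)
  p <- 2 * stats::pnorm(-abs(z))
  padj <- rep(NA_real_, length(p))
  usable <- !is.na(p)
  padj[usable] <- stats::p.adjust(p[usable], method = "BH")
  mask <- !is.na(padj) & padj < alpha
  structure(list(
    mask = array(mask, dim(amplitude_map)), alpha = alpha,
    n_voxels = sum(mask),
    p_adjusted = array(padj, dim(amplitude_map))
  ), class = "roi_mask")
}

#' Cortical tuning metric: inverse mean period over the ROI
#'
#' Averages the fitted period over the voxels of the region of interest and
#' returns the inverse, `1 / mean(period)` (units 1/s). Larger values mean
#' a shorter mean period, i.e. sharper and more digit-selective activation
#' during the movement cycle. `aggregate = "mean_inverse"` instead averages
#' the per-voxel inverse periods, `mean(1 / period)`.
#'
#' @param period_map 3D array of per-voxel periods, seconds.
#' @param roi a [define_roi()] result (or a logical array).
#' @param aggregate `"inverse_mean"` (default) or `"mean_inverse"`.
#' @return tuning metric, 1/s.
#' @export
tuning_metric <- function(period_map, roi,
                          aggregate = c("inverse_mean", "mean_inverse")) {
  aggregate <- match.arg(aggregate)
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  stopifnot(identical(dim(mask), dim(period_map)))
  periods <- period_map[mask]
  periods <- periods[is.finite(periods)]
  if (length(periods) == 0) stop("empty ROI: tuning metric undefined")
  if (aggregate == "inverse_mean") 1 / mean(periods) else mean(1 / periods)
}

#' In-scanner button-press behavioral metrics
#'
#' Press rate is computed from inter-press intervals after excluding
#' statistical outliers (intervals beyond +/- 2 standard deviations of the
#' mean interval); accuracy is the fraction of cues answered by a press
#' beginning within 400 ms of the cue.
#'
#' @param presses press-onset timestamps, seconds.
#' @param cues cue timestamps, seconds (256 per task variant in the
#'   standard protocol).
#' @param window_s accuracy window, seconds.
#' @return list with `mean_ipi` (s), `rate` (presses/s, `1/mean_ipi`),
#'   `accuracy` (proportion of cues hit), `n_intervals_used` and
#'   `n_outliers` excluded. With no presses, accuracy is 0 and the rate
#'   fields are NA.
#' @export
press_metrics <- function(presses, cues, window_s = 0.4) {
  presses <- sort(presses)
  acc <- if (length(presses) == 0) 0 else {
    mean(vapply(cues, function(cue) {
      any(presses >= cue & presses <= cue + window_s)
    }, logical(1)))
  }
  if (length(presses) < 2) {
    return(list(mean_ipi = NA_real_, rate = NA_real_, accuracy = acc,
                n_intervals_used = 0L, n_outliers = 0L))
  }
  ipi <- diff(presses)
  keep <- abs(ipi - mean(ipi)) <= 2 * stats::sd(ipi)
  mean_ipi <- mean(ipi[keep])
  list(mean_ipi = mean_ipi, rate = 1 / mean_ipi, accuracy = acc,
       n_intervals_used = sum(keep), n_outliers = sum(!keep))
}
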