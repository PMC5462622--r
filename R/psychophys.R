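#' Per-ISI response proportions from a temporal-order-judgment trial table
#'
#' Collapses raw trials into the proportion of "middle-first" judgments at
#' each interstimulus interval. The sign convention follows the task:
#' positive ISI means the middle finger was stimulated first. Trials with
#' response `"no_response"` are dropped (with the count returned); any other
#' unknown response code is an error.
#'
#' @param trials data frame with columns `isi_ms` and `response`
#'   (`"middle_first"`, `"index_first"`, optionally `"no_response"`).
#' @return data frame with columns `isi_ms`, `n_trials`, `n_middle_first`,
#'   `prop_middle_first`, sorted by ISI; attribute `n_dropped` holds the
#'   count of dropped no-response trials.
#' @export
aggregate_proportions <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("isi_ms", "response") %in% names(trials)))
  known <- c("middle_first", "index_first", "no_response")
  bad <- setdiff(unique(trials$response), known)
  if (length(bad) > 0) stop("unknown response codes: ", paste(bad, collapse = ", "))
  n_dropped <- sum(trials$response == "no_response")
  trials <- trials[trials$response != "no_response", , drop = FALSE]
  if (nrow(trials) == 0) stop("no scorable trials")
  isis <- sort(unique(trials$isi_ms))
  agg <- do.call(rbind, lapply(isis, function(i) {
    r <- trials$response[trials$isi_ms == i]
    if (length(r) == 0) stop("ISI cell with no trials: ", i)
    data.frame(isi_ms = i, n_trials = length(r),
               n_middle_first = sum(r == "middle_first"),
               prop_middle_first = mean(r == "middle_first"))
  }))
  attr(agg, "n_dropped") <- n_dropped
  agg
}

#' Fit a logistic psychometric function to per-ISI proportions
#'
#' Unweighted least-squares fit of
#' `p(ISI) = 1 / (1 + exp(-(ISI - mu) / slope))` to the observed
#' proportions, matching the usual curve-fitting practice of reporting an
#' r-squared for the psychometric fit (an option for binomial maximum
#' likelihood is provided). Fits with `r_squared <= 0.4` are flagged as
#' rejected by the quality-of-fit criterion.
#'
#' @param proportions output of [aggregate_proportions()] (or any data frame
#'   with `isi_ms` and `prop_middle_first`, plus `n_trials` for the
#'   likelihood method).
#' @param method `"ls"` (default) or `"ml"` for binomial likelihood.
#' @param r2_min quality-of-fit threshold on r-squared.
#' @return An object of class `psychometric_fit`: `mu` (point of subjective
#'   simultaneity, ms), `slope` (logistic scale, ms), `r_squared`, `jnd`
#'   (ms, `slope * log(3)`), `ok` (passes the r-squared criterion),
#'   `identifiable`, `method`.
#' @export
fit_logistic <- function(proportions, method = c("ls", "ml"), r2_min = 0.4) {
  method <- match.arg(method)
  stopifnot(all(c("isi_ms", "prop_middle_first") %in% names(proportions)))
  x <- proportions$isi_ms
  p <- proportions$prop_middle_first
  if (length(unique(x)) < 4 || min(x) >= 0 || max(x) <= 0) {
    stop("need >= 4 distinct ISIs spanning both signs")
  }
  if (all(p == p[1])) {
    return(structure(list(mu = NA_real_, slope = NA_real_,
                          r_squared = NA_real_, jnd = NA_real_, ok = FALSE,
                          identifiable = FALSE, method = method),
                     class = "psychometric_fit"))
  }
  # starting values from the probit-free logit line on clamped proportions
  pc <- pmin(pmax(p, 0.02), 0.98)
  lin <- stats::lm(stats::qlogis(pc) ~ x)
  s0 <- max(1, 1 / abs(stats::coef(lin)[2]))
  m0 <- -stats::coef(lin)[1] * s0 * sign(stats::coef(lin)[2])

  obj <- if (method == "ls") {
    function(par) sum((p - stats::plogis((x - par[1]) / exp(par[2])))^2)
  } else {
    n <- proportions$n_trials
    k <- round(p * n)
    function(par) {
      ph <- pmin(pmax(stats::plogis((x - par[1]) / exp(par[2])), 1e-9), 1 - 1e-9)
      -sum(k * log(ph) + (n - k) * log(1 - ph))
    }
  }
  fit <- stats::optim(c(m0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- unname(fit$par[1]); slope <- unname(exp(fit$par[2]))
  fitted <- stats::plogis((x - mu) / slope)
  ss_res <- sum((p - fitted)^2)
  ss_tot <- sum((p - mean(p))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  structure(list(mu = mu, slope = slope, r_squared = r2,
                 jnd = slope * log(3), ok = !is.na(r2) && r2 > r2_min,
                 identifiable = TRUE, method = method),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric_fit: mu = %.2f ms, slope = %.2f ms, r2 = %.3f, JND = %.2f ms%s\n",
              x$mu, x$slope, x$r_squared, x$jnd,
              if (isTRUE(x$ok)) "" else " [fit rejected]"))
  invisible(x)
}

#' Just-noticeable difference from a fitted psychometric function
#'
#' The JND is half the ISI span between the 25% and 75% points of the
#' fitted curve. For the logistic parameterization the quantile at
#' probability p is `mu + slope * log(p / (1 - p))`, so the JND reduces to
#' the closed form `slope * log(3)`, independent of `mu`. Smaller JND means
#' higher perceptual acuity.
#'
#' @param fit a [fit_logistic()] result.
#' @return JND in ms.
#' @export
compute_jnd <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!isTRUE(fit$identifiable)) stop("fit is not identifiable; no JND")
  isi75 <- fit$mu + fit$slope * log(0.75 / 0.25)
  isi25 <- fit$mu + fit$slope * log(0.25 / 0.75)
  (isi75 - isi25) / 2
}
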