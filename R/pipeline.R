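#' Default end-to-end run configuration
#'
#' Returns the demo configuration: a simulated cohort of 12 subjects at the
#' metric level (set `raw_level = TRUE` to synthesize and re-analyze the raw
#' fMRI/TOJ/MRS streams per subject), the standard digit-cycling task
#' design, default QC and FDR settings, and bootstrap parameters.
#'
#' @param ... named overrides of any configuration field.
#' @return a named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    n_subjects = 12,
    seed = 7,
    raw_level = FALSE,
    path_a = 0.7, path_b = -0.6, path_c_prime = 0,
    noise_sd_m = 0.5, noise_sd_y = 0.5,
    alpha = 0.01,
    qc_mode = "default",
    n_boot = 5000,
    tr = 1.5, block_s = 8, n_cycles = 8, digits = 2:5,
    grid_shape = c(4, 4, 1), grid_noise_sd = 0.3,
    out_dir = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg a configuration list.
#' @return the validated config, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop("config field '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 4, "n_subjects", ">= 4 required")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed", "integer required")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1, "alpha", "must be in (0,1)")
  chk(cfg$qc_mode %in% c("default", "strict"), "qc_mode", "must be 'default' or 'strict'")
  chk(is.numeric(cfg$n_boot) && cfg$n_boot >= 1000, "n_boot", ">= 1000 required")
  chk(is.numeric(cfg$tr) && cfg$tr > 0, "tr", "positive number required")
  chk(length(cfg$grid_shape) == 3, "grid_shape", "length-3 vector required")
  invisible(cfg)
}

# Deterministic per-stage sub-seed derived from the global seed. Kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 2654435761 + h * 97) %% 2147483647L)
}

# Build an MRS table realizing given target GABA:Cr / Glu:Cr ratios exactly,
# so the tissue-correction chain recovers them (raw-level pipeline mode).
mrs_table_for_targets <- function(subjects, gaba_cr, glu_cr, seed) {
  set.seed(seed)
  n <- length(subjects)
  gm <- stats::runif(n, 0.4, 0.5); wm <- stats::runif(n, 0.3, 0.4)
  csf <- 1 - gm - wm
  cr <- stats::rnorm(n, 4.5, 0.2); pcr <- stats::rnorm(n, 3.5, 0.2)
  tcr <- (cr + pcr) / (gm + wm)               # corrected total creatine
  gaba_abs <- gaba_cr * tcr * gm
  glu_abs <- glu_cr * tcr * gm
  rows <- Map(function(met, abs_vec, crlb) {
    data.frame(subject = subjects, metabolite = met, absolute = abs_vec,
               crlb = crlb, fwhm_hz = 9, snr = 70, gm = gm, wm = wm, csf = csf)
  }, c("GABA", "Glu", "Cr", "PCr"),
     list(gaba_abs, glu_abs, cr, pcr), c(12, 4, 2, 3))
  do.call(rbind, rows)
}

# Recompute one subject's tuning metric from simulated forward+backward runs.
subject_tuning_from_raw <- function(width, design_f, design_b, grid_shape,
                                    noise_sd, alpha, seed) {
  g <- sim_grid(grid_shape, tuning_width = width, noise_sd = noise_sd,
                digits = design_f$digits)
  runf <- simulate_fmri_run(g, design_f, seed = seed)
  runb <- simulate_fmri_run(g, design_b, seed = seed + 1L)
  mf <- fit_tuning_maps(runf$img, design_f)
  mb <- fit_tuning_maps(runb$img, design_b)
  comb <- combine_runs(mf, mb)
  amp <- comb$amplitude
  amp[!is.na(amp)] <- pmin(amp[!is.na(amp)], 0.999)  # r scale for Fisher z
  roi <- define_roi(amp, n_timepoints = design_f$n_volumes, alpha = alpha)
  if (roi$n_voxels == 0) return(NA_real_)
  tuning_metric(comb$period, roi)
}

#' Per-subject metric table from a simulated cohort
#'
#' Metric-level mode returns the generator's table directly. Raw-level mode
#' re-derives every metric through the full pipeline: forward and backward
#' digit-cycling runs are simulated per subject and analyzed with the
#' traveling-wave chain into a tuning metric; temporal-order-judgment
#' trials are simulated and fitted into a JND; and an MRS table realizing
#' the subject's neurochemical ground truth is pushed through QC, tissue
#' correction and the creatine ratio.
#'
#' @param cfg a [default_config()]-style configuration.
#' @return data frame with columns `subject`, `gaba_cr`, `glu_cr`,
#'   `tuning`, `jnd`.
#' @export
build_metrics <- function(cfg) {
  validate_config(cfg)
  truth <- cohort_truth(cfg$n_subjects, cfg$path_a, cfg$path_b,
                        cfg$path_c_prime, cfg$noise_sd_m, cfg$noise_sd_y)
  cohort <- simulate_cohort(truth, seed = derive_seed(cfg$seed, "cohort"),
                            raw_level = cfg$raw_level)
  set.seed(derive_seed(cfg$seed, "glu"))
  glu <- 1.1 + 0.08 * stats::rnorm(cfg$n_subjects)  # glutamate: no true link
  if (!cfg$raw_level) {
    return(data.frame(subject = cohort$subject, gaba_cr = cohort$gaba_cr,
                      glu_cr = glu, tuning = cohort$tuning, jnd = cohort$jnd))
  }
  design_f <- task_design(cfg$tr, cfg$block_s, cfg$n_cycles, cfg$digits, "forward")
  design_b <- task_design(cfg$tr, cfg$block_s, cfg$n_cycles, cfg$digits, "backward")
  tuning <- vapply(seq_len(cfg$n_subjects), function(i) {
    subject_tuning_from_raw(cohort$tuning_width[i], design_f, design_b,
                            cfg$grid_shape, cfg$grid_noise_sd, cfg$alpha,
                            seed = derive_seed(cfg$seed, paste0("fmri", i)))
  }, numeric(1))
  jnd <- vapply(seq_len(cfg$n_subjects), function(i) {
    obs <- toj_observer(mu = 0, slope = cohort$toj_slope[i])
    tr <- simulate_toj_trials(obs, seed = derive_seed(cfg$seed, paste0("toj", i)))
    fit <- fit_logistic(aggregate_proportions(tr))
    if (isTRUE(fit$identifiable)) compute_jnd(fit) else NA_real_
  }, numeric(1))
  mrs <- mrs_ratios(mrs_table_for_targets(cohort$subject, cohort$gaba_cr, glu,
                                          seed = derive_seed(cfg$seed, "mrs")),
                    mode = cfg$qc_mode)
  out <- merge(mrs$ratios,
               data.frame(subject = cohort$subject, tuning = tuning, jnd = jnd),
               by = "subject")
  out[order(out$subject), ]
}

#' Statistics report for a per-subject metric table
#'
#' Computes every statistic of the inferential layer for a cohort table:
#' Pearson correlations (GABA:Cr and Glu:Cr against tuning and JND, and
#' tuning against JND), Hittner comparisons of the overlapping GABA vs
#' glutamate correlations, the conjunction/omnibus compound verdict,
#' GABA partial correlations controlling for Glu:Cr, and the bootstrap
#' mediation of GABA -> tuning -> JND.
#'
#' @param metrics data frame with columns `gaba_cr`, `glu_cr`, `tuning`,
#'   `jnd` (rows = subjects, complete cases used).
#' @param n_boot bootstrap resamples for mediation.
#' @param seed integer seed.
#' @param alpha level for the compound verdict.
#' @return a nested list (class `somatotune_report`).
#' @export
analyze_metrics <- function(metrics, n_boot = 5000, seed = 7, alpha = 0.05) {
  need <- c("gaba_cr", "glu_cr", "tuning", "jnd")
  missing_f <- setdiff(need, names(metrics))
  if (length(missing_f) > 0) {
    stop("metrics table missing column(s): ", paste(missing_f, collapse = ", "))
  }
  metrics <- metrics[stats::complete.cases(metrics[need]), , drop = FALSE]
  n <- nrow(metrics)
  cors <- list(
    gaba_tuning = pearson_with_p(metrics$gaba_cr, metrics$tuning),
    gaba_jnd = pearson_with_p(metrics$gaba_cr, metrics$jnd),
    tuning_jnd = pearson_with_p(metrics$tuning, metrics$jnd),
    glu_tuning = pearson_with_p(metrics$glu_cr, metrics$tuning),
    glu_jnd = pearson_with_p(metrics$glu_cr, metrics$jnd)
  )
  hittner <- list(
    tuning_gaba_vs_glu = hittner_test(
      cors$gaba_tuning$r, cors$glu_tuning$r,
      stats::cor(metrics$gaba_cr, metrics$glu_cr), n),
    jnd_gaba_vs_glu = hittner_test(
      cors$gaba_jnd$r, cors$glu_jnd$r,
      stats::cor(metrics$gaba_cr, metrics$glu_cr), n)
  )
  compound <- conjunction_omnibus(
    predicted_ps = c(cors$gaba_tuning$p_two_tailed, cors$gaba_jnd$p_two_tailed,
                     cors$tuning_jnd$p_two_tailed),
    unpredicted_ps = c(cors$glu_tuning$p_two_tailed, cors$glu_jnd$p_two_tailed),
    alpha = alpha)
  partials <- list(
    gaba_tuning_ctrl_glu = partial_correlation(metrics$gaba_cr, metrics$tuning,
                                               metrics$glu_cr),
    gaba_jnd_ctrl_glu = partial_correlation(metrics$gaba_cr, metrics$jnd,
                                            metrics$glu_cr)
  )
  med <- mediate(metrics$gaba_cr, metrics$tuning, metrics$jnd,
                 n_boot = n_boot, seed = seed)
  structure(list(n = n, correlations = cors, hittner = hittner,
                 compound = compound, partials = partials, mediation = med,
                 alpha = alpha, seed = seed),
            class = "somatotune_report")
}

#' @export
print.somatotune_report <- function(x, ...) {
  cat(sprintf("somatotune report (n = %d)\n", x$n))
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    cat(sprintf("  %-12s r = %+.3f, p = %.4f\n", nm, cr$r, cr$p_two_tailed))
  }
  for (nm in names(x$hittner)) {
    h <- x$hittner[[nm]]
    cat(sprintf("  Hittner %-18s Z = %+.2f, p1 = %.4f, p2 = %.4f\n",
                nm, h$z_stat, h$p_one_tailed, h$p_two_tailed))
  }
  cat(sprintf("  conjunction max p = %.4f, omnibus min p = %.4f -> %s\n",
              x$compound$conjunction_statistic, x$compound$omnibus_statistic,
              if (x$compound$reject) "reject compound null" else "retain"))
  print(x$mediation)
  invisible(x)
}

# Flatten the report for JSON serialization.
report_to_list <- function(rep) {
  strip <- function(obj) unclass(obj)
  list(
    n = rep$n,
    correlations = lapply(rep$correlations, strip),
    hittner = lapply(rep$hittner, strip),
    compound = rep$compound,
    partials = lapply(rep$partials, strip),
    mediation = strip(rep$mediation),
    alpha = rep$alpha, seed = rep$seed
  )
}

#' Run the pipeline end to end and write the report bundle
#'
#' Simulates (or re-derives, in raw-level mode) the per-subject metrics,
#' computes the full statistics report and writes `metrics.csv`,
#' `report.json`, `report.txt` and `config.yaml` (with seed and config
#' hash for provenance) into `out_dir`. Runs are byte-identical given the
#' same configuration and seed; inputs on disk are never mutated.
#'
#' @param cfg a [default_config()]-style configuration; `out_dir` may be
#'   NULL to skip writing.
#' @return list with `metrics`, `report` and `paths` (written files).
#' @export
run_end_to_end <- function(cfg = default_config()) {
  validate_config(cfg)
  metrics <- build_metrics(cfg)
  rep <- analyze_metrics(metrics, n_boot = cfg$n_boot,
                         seed = derive_seed(cfg$seed, "stats"))
  paths <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p_metrics <- file.path(cfg$out_dir, "metrics.csv")
    write_csv_exact(metrics, p_metrics)
    p_json <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(report_to_list(rep), p_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    p_txt <- file.path(cfg$out_dir, "report.txt")
    sink(p_txt); print(rep); sink()
    cfg_plain <- unclass(cfg)
    cfg_plain$out_dir <- NULL
    cfg_plain$config_hash <- substr(
      tools::md5sum(p_metrics)[[1]], 1, 12)
    p_cfg <- file.path(cfg$out_dir, "config.yaml")
    yaml::write_yaml(cfg_plain, p_cfg)
    paths <- c(metrics = p_metrics, report_json = p_json,
               report_txt = p_txt, config = p_cfg)
  }
  list(metrics = metrics, report = rep, paths = paths)
}

#' Full-precision CSV round trip
#'
#' Base `write.csv` serializes doubles at 15 significant digits, which does
#' not always reproduce the same binary value on re-read. These helpers
#' write numeric columns at 17 significant digits (`%.17g`), the minimal
#' precision guaranteeing an exact double round trip, so
#' `read_csv_exact(write_csv_exact(x)) == x` bit for bit.
#'
#' @param x data frame.
#' @param path CSV path.
#' @return `write_csv_exact` returns `path` invisibly; `read_csv_exact`
#'   returns the data frame.
#' @export
write_csv_exact <- function(x, path) {
  y <- as.data.frame(lapply(x, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE)
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_csv_exact
#' @export
read_csv_exact <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of [default_config()] fields.
#' @return validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
  cfg
}
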