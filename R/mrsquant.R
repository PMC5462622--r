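#' Quality-filter an MRS metabolite table
#'
#' A record is excluded if and only if it violates any exclusion rule:
#' Cramér-Rao lower bound above 50% (strictly), water linewidth (FWHM)
#' above 15 Hz, or spectral SNR below 40. `mode = "strict"` additionally
#' tightens the CRLB rule to keep only records with CRLB < 30%.
#'
#' @param records data frame with columns `crlb`, `fwhm_hz`, `snr` (plus
#'   anything else, passed through).
#' @param mode `"default"` or `"strict"`.
#' @param crlb_max,fwhm_max,snr_min rule thresholds.
#' @return list with `kept` (rows passing every rule), `excluded`
#'   (failing rows) and `log` (data frame naming the violated rule(s) per
#'   excluded row).
#' @export
qc_filter <- function(records, mode = c("default", "strict"),
                      crlb_max = 50, fwhm_max = 15, snr_min = 40) {
  mode <- match.arg(mode)
  need <- c("crlb", "fwhm_hz", "snr")
  missing_f <- setdiff(need, names(records))
  if (length(missing_f) > 0) {
    stop("missing QC field(s): ", paste(missing_f, collapse = ", "))
  }
  if (anyNA(records[need])) stop("missing QC field values (NA)")
  bad_crlb <- if (mode == "strict") records$crlb >= 30 else records$crlb > crlb_max
  bad_fwhm <- records$fwhm_hz > fwhm_max
  bad_snr <- records$snr < snr_min
  bad <- bad_crlb | bad_fwhm | bad_snr
  rules <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(if (bad_crlb[i]) "crlb", if (bad_fwhm[i]) "fwhm",
            if (bad_snr[i]) "snr"), collapse = "+")
  }, character(1))
  log <- data.frame(row = which(bad), rule = rules[bad])
  if ("subject" %in% names(records)) log$subject <- records$subject[bad]
  if ("metabolite" %in% names(records)) log$metabolite <- records$metabolite[bad]
  list(kept = records[!bad, , drop = FALSE],
       excluded = records[bad, , drop = FALSE],
       log = log)
}

#' Tissue-correct a metabolite estimate for gray-matter fraction
#'
#' GABA and glutamate are predominantly gray-matter metabolites, so their
#' absolute estimates are scaled up by the inverse of the gray-matter
#' fraction of the voxel: `corrected = absolute / (gm / (gm + wm + csf))`.
#' With a pure-GM voxel the factor is 1; less GM gives a larger factor
#' (standard partial-volume scaling).
#'
#' @param absolute absolute concentration estimate (institutional units).
#' @param gm,wm,csf tissue fractions (must sum to 1 within 1e-6; gm > 0).
#' @return list with `corrected` and the `factor` applied.
#' @export
tissue_correct <- function(absolute, gm, wm, csf) {
  if (abs(gm + wm + csf - 1) > 1e-6) stop("tissue fractions must sum to 1")
  if (gm <= 0) stop("gray-matter fraction must be positive for GM correction")
  factor <- (gm + wm + csf) / gm
  list(corrected = absolute * factor, factor = factor)
}

#' Tissue-correct total creatine for brain-tissue fraction
#'
#' Total creatine (creatine + phosphocreatine) is distributed over all
#' brain tissue, so the summed estimate is scaled by the inverse brain
#' fraction: `(Cr + PCr) / ((gm + wm) / (gm + wm + csf))`. With no CSF the
#' factor is 1; the factor is always >= 1.
#'
#' @param cr_absolute,pcr_absolute absolute Cr and PCr estimates.
#' @param gm,wm,csf tissue fractions (sum to 1; gm + wm > 0).
#' @return list with `corrected` and the `factor` applied.
#' @export
creatine_correct <- function(cr_absolute, pcr_absolute, gm, wm, csf) {
  if (abs(gm + wm + csf - 1) > 1e-6) stop("tissue fractions must sum to 1")
  if (gm + wm <= 0) stop("brain-tissue fraction must be positive")
  factor <- (gm + wm + csf) / (gm + wm)
  list(corrected = (cr_absolute + pcr_absolute) * factor, factor = factor)
}

#' Ratio of a corrected metabolite to corrected total creatine
#'
#' @param metab corrected metabolite concentration.
#' @param cr corrected total creatine (> 0).
#' @return the ratio.
#' @export
ratio_to_creatine <- function(metab, cr) {
  if (cr <= 0) stop("total creatine must be positive")
  metab / cr
}

#' Per-subject GABA:Cr and Glu:Cr ratios from a metabolite table
#'
#' Applies [qc_filter()] at the spectrum level (a subject is dropped when
#' any of its rows fails QC), then tissue-corrects GABA/Glu by GM fraction
#' and total creatine by brain fraction, and forms the ratios. Set
#' `ratio = FALSE` to obtain the tissue-corrected raw concentrations
#' instead of creatine ratios.
#'
#' @param records table as produced by [simulate_mrs_table()] (long format,
#'   one row per subject x metabolite).
#' @param mode QC mode, `"default"` or `"strict"`.
#' @param ratio divide by corrected total creatine (default TRUE).
#' @return list with `ratios` (data frame: `subject`, `gaba_cr`, `glu_cr`)
#'   and `qc` (the exclusion log).
#' @export
mrs_ratios <- function(records, mode = "default", ratio = TRUE) {
  qc <- qc_filter(records, mode = mode)
  kept <- qc$kept
  bad_subjects <- unique(qc$excluded$subject)
  kept <- kept[!(kept$subject %in% bad_subjects), , drop = FALSE]
  subjects <- unique(kept$subject)
  rows <- lapply(subjects, function(s) {
    sub <- kept[kept$subject == s, ]
    get <- function(m) sub[sub$metabolite == m, , drop = FALSE]
    gaba <- get("GABA"); glu <- get("Glu"); cr <- get("Cr"); pcr <- get("PCr")
    if (any(vapply(list(gaba, glu, cr, pcr), nrow, integer(1)) != 1)) return(NULL)
    g <- tissue_correct(gaba$absolute, gaba$gm, gaba$wm, gaba$csf)$corrected
    e <- tissue_correct(glu$absolute, glu$gm, glu$wm, glu$csf)$corrected
    tcr <- creatine_correct(cr$absolute, pcr$absolute, cr$gm, cr$wm, cr$csf)$corrected
    if (ratio) {
      data.frame(subject = s, gaba_cr = ratio_to_creatine(g, tcr),
                 glu_cr = ratio_to_creatine(e, tcr))
    } else {
      data.frame(subject = s, gaba_cr = g, glu_cr = e)
    }
  })
  list(ratios = do.call(rbind, rows), qc = qc$log)
}
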