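Package: somatotune
Title: Traveling-Wave Cortical Tuning, Tactile Psychophysics and MRS
    Neurochemistry Analysis
Version: 0.1.0
Authors@R:
    person("Somatotune", "Developers", email = "maintainer@somatotune.org",
           role = c("aut", "cre"))
Description: Tools for relating cortical inhibition to functional
    architecture and perception in human somatosensory cortex. Implements
    the traveling-wave (phase-encoded) analysis of digit-cycling fMRI runs
    (lag-shifted gamma-convolved reference models, voxel-wise tuning
    profiles, sinusoid fits, FDR-defined regions of interest and the
    1/period cortical tuning metric), logistic psychometric fitting of
    temporal-order-judgment data with just-noticeable-difference (JND)
    estimation, quality filtering and tissue correction of MRS metabolite
    tables into GABA:Cr and Glu:Cr ratios, and the inferential layer that
    links them: Pearson correlations, Hittner's dependent-correlation
    comparison, partial correlation, conjunction/omnibus compound tests,
    bootstrap mediation (proportion mediated, Sobel test, kappa-squared)
    and ICC(A,1) reproducibility. A synthetic-data module generates all
    three raw-data streams with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
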