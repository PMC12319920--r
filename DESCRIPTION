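Package: dfkurtosis
Title: Diffusion Functional MRI: Fast Kurtosis Mapping and Time-Dependence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for task-based diffusion functional MRI of the
    rodent brain. Schedules block-design acquisitions with alternating rest and
    stimulus intervals, simulates diffusion-weighted and BOLD series from
    two-compartment exchange substrates with Rician noise, estimates voxel-wise
    mean diffusivity (MD) and mean kurtosis (MK) per condition and diffusion
    time with a fast two-shell nine-direction estimator, fits and compares
    structural-disorder and Karger-exchange models of the MD and MK
    diffusion-time dependence by corrected AIC, and produces ROI-level
    rest-versus-stimulus statistics with linear mixed models and false
    discovery rate control, alongside a boxcar GLM analysis of the BOLD arm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
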