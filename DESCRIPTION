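Package: pwvfmri
Title: Aortic Stiffness and Resting-State fMRI Fluctuation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the association between aortic pulse-wave
    velocity (PWV) and resting-state fMRI signal fluctuations measured with a
    dual-echo pseudo-continuous arterial spin labeling (pCASL) sequence.
    Provides a seeded synthetic-cohort generator (covariates, aortic flow
    waveforms, interleaved tag/control dual-echo series, tissue masks, vessel
    atlases), time-to-foot PWV estimation from flow waveforms, BOLD/CBF signal
    separation by surround averaging and subtraction with aCompCor-style
    physiological denoising and zero-phase band-pass filtering, fluctuation
    variance maps and general-kinetic-model CBF quantification, intrinsic
    connectivity contrast maps, voxelwise GLM inference with threshold-free
    cluster enhancement and Freedman-Lane permutation FWE correction,
    vessel-probability regression, and Preacher-Hayes bootstrap mediation
    analysis, orchestrated by a configurable deterministic pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
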