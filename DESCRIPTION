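Package: musedecode
Title: fMRI-Informed EEG Source Decoding and Reconstruction of Heard Music
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, end-to-end pipeline for reconstructing the music a
    listener heard from multichannel EEG, using fMRI statistical maps to
    select cortical dipole locations. Provides a synthetic joint EEG-fMRI
    music-listening data generator, an analytic three-shell spherical head
    model and leadfield, mass-univariate GLM T-contrast mapping with greedy
    minimum-distance dipole selection, SOBI blind source separation, an
    eLORETA distributed inverse solution with per-component source-projection
    feature construction, a bidirectional LSTM sequence-regression decoder
    trained in a run-wise cross-fold scheme, and evaluation by time/frequency
    correlation, spectrogram structural similarity, bootstrap null testing,
    and rank-accuracy identification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
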