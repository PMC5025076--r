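Package: mibci
Title: Automated ICA Filter Optimization for Motor-Imagery Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and optimizing independent component analysis (ICA)
    based motor-imagery brain-computer interfaces from few-channel EEG. Implements
    single-trial Infomax ICA with natural-gradient updates and sub/super-Gaussian
    switching, automated detection of motor-related independent components from
    mixing-matrix topographies, two-round bad-trial rejection, a zero-training
    minimum-variance classifier exploiting event-related desynchronization, top-m
    trial concatenation (ICA-T) and sliding-window (ICA-S) filter builders, a
    one-versus-rest common spatial patterns baseline, and an accuracy-matrix tool
    that localizes artifact segments within trials. A forward-model simulator of
    three-class motor-imagery EEG with ground-truth mixing and controllable
    artifacts is included as a test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    MASS,
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    ggplot2,
    generics,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
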