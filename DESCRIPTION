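Package: winbci
Title: Time-Window Effects in Recurrent Classification of Eyes-Open/Eyes-Closed EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how the length of the
    classification time window affects eyes-open versus eyes-closed state decoding
    from low-cost wireless EEG. Provides a protocol-shaped synthetic EEG generator
    with ground-truth blink and artifact annotations, regression-based eye-blink
    denoising with an AFZ reference built from the frontal channels, Butterworth
    band-pass filtering, z-score based automatic artifact rejection, Morlet-wavelet
    alpha-band (8-12 Hz) power extraction at the occipital electrodes, sliding-window
    sequence dataset construction, an LSTM sequence classifier (with a tap-delay RNN
    and a roster of classical pointwise classifiers for comparison), repeated
    train/validation evaluation with Friedman and pairwise Wilcoxon signed-rank
    window comparisons, and a streaming classification simulator that measures
    state-transition detection delays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    MASS,
    e1071,
    rpart,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
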