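Package: rppgfuse
Title: Contact-Quality Remote Photoplethysmogram Construction and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Constructs a contact-quality remote photoplethysmogram (rPPG)
    from facial-video colour traces by fusing the outputs of four classical
    chrominance/source-separation extractors (CHROM, POS, LGI, ICA) with a
    recurrent (LSTM) sequence model trained against reference contact PPG.
    Includes a seeded synthetic-data generator emulating quasi-periodic PPG
    waveforms and noisy RGB observations across activity regimes, landmark
    patch-mean extraction and spatiotemporal maps, the full signal
    conditioning chain (linear detrend, zero-phase sixth-order Butterworth
    0.65-4 Hz bandpass, cubic resampling, low-variance rejection, histogram
    equalization, 10-second windowing, min-max normalization), evaluation
    metrics (dynamic time warping, Pearson correlation, RMSE, Welch-based
    heart-rate error), and a method-ranking procedure based on the Friedman
    test with Nemenyi post-hoc comparisons and Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
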