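Package: dysditect
Title: Dyslexia Screening from Handwritten Chinese Dictation Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Participant-level screening for Chinese developmental dyslexia
    from the ordered sequence of 96 handwritten characters produced in a
    word dictation task. Implements the DysDiTect model family (shared CNN
    feature extractor, sinusoidal positional encoding, bidirectional LSTM,
    multi-head self-attention, and a condensation classifier that can use
    grade information) together with its 16-variant ablation framework, the
    scanned-page preprocessing chain (box detection, cropping, binarization,
    rescaling), a calibrated synthetic dictation-cohort generator, stratified
    splitting, the training loop with schedule and early stopping, evaluation
    metrics with grade banding, and attention-map analyses (attained-weight
    entropy and ICC(3,k)). Neural layers are implemented natively in R and
    C++ with hand-derived backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
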