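Package: affecthr
Title: Heart-Rate-Based Affect Recognition with Semi-Automated Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for three-class affect recognition (negative,
    positive, neutral) from smartwatch heart-rate streams, as used for in-the-wild
    monitoring of children on the autism spectrum. Provides a synthetic cohort
    generator driven by a latent semi-Markov affect process, semi-automated
    emotion annotation of heart-rate windows from a facial-expression prediction
    stream with confidence-based human escalation, from-scratch orthonormal Haar
    discrete-wavelet-transform feature extraction, and intra-/inter-subject
    evaluation of SVM, k-NN and random-forest classifiers under stratified
    ten-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    e1071,
    class,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
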