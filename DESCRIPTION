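Package: emgpipe
Title: Surface EMG Hand-Gesture Feature Extraction and Classifier Benchmarking
Version: 0.1.0
Authors@R: person("emgpipe", "developers", email = "emgpipe@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for surface electromyography (sEMG)
    hand-gesture analysis with eight-channel armband-style recordings sampled
    at 200 Hz. Provides a seeded synthetic signal generator with labeled
    gesture bursts, a preprocessing chain (zero-phase Butterworth band-pass
    filtering, per-channel normalization, rectification, moving-RMS envelope
    extraction) with segmentation into fixed-length labeled windows, ten
    classical time-domain feature operators (min, max, SD, zero crossings,
    RMS, average amplitude change, amplitude of first burst, mean absolute
    value, waveform length, Willison amplitude), feature engineering via
    z-score standardization and PCA with an explained-variance retention
    target, and a multi-classifier benchmark (multinomial logistic
    regression, linear and RBF-kernel support vector machines, k-nearest
    neighbors, random forest) under stratified five-fold cross-validation
    with per-class and overall precision, recall, F1, accuracy and
    one-vs-rest ROC-AUC.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    FNN,
    glmnet,
    jsonlite,
    quadprog,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
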