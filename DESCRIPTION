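Package: ramanbiopsy
Title: Raman Optical-Biopsy Preprocessing, Feature Filtering and Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for intraoperative Raman
    optical biopsy of brain tissue. Provides preprocessing of raw
    spectra (ambient-background subtraction, saturation exclusion,
    Savitzky-Golay smoothing, fluorescence baseline removal by a
    fitted sum of Morlet wavelets, range cropping and
    integral-intensity normalization), per-wavenumber Fisher-criterion
    (one-way ANOVA F) feature filtering mapped onto biochemical bands,
    PCA projection and RBF-kernel SVM classification of tissue classes
    (normal white matter, tumor edge, tumor center), and a synthetic
    spectrum generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    signal,
    e1071,
    pracma,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
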