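Package: rlscca
Title: SSVEP Decoding by Recursive Least Squares Noise Cancellation and
    Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes steady-state visual evoked potential (SSVEP)
    brain-computer interface recordings. Occipital EEG channels are
    enhanced by recursive least squares (RLS) adaptive cancellation of the
    background activity estimated from a non-occipital mean reference, then
    the stimulation frequency is classified by the maximal canonical
    correlation against sine/cosine harmonic templates. Includes common
    average referencing, zero-phase band-pass filtering and decimation,
    block-wise K-fold evaluation with accuracy, information transfer rate
    and narrowband SNR, readers and writers for 4-D trial tensors
    (MAT/HDF5), and a synthetic SSVEP generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
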