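Package: kibci
Title: Kinesthetic-Illusion Motor-Imagery EEG Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for lower-limb motor-imagery
    brain-computer interface (BCI) studies with kinesthetic illusion.
    Generates synthetic 16-channel sensorimotor EEG sessions with a
    four-condition cue paradigm (rest, vibration rest, motor imagery with
    and without tendon-vibration illusion) as 1/f background plus alpha and
    beta rhythms with configurable event-related desynchronization (ERD);
    provides epoching and peak-to-peak artifact rejection, ERD time-course
    and topography summaries, imaginary-coherency connectivity matrices,
    filter-bank common spatial pattern (FBCSP) feature extraction with
    mutual-information feature selection and RBF-SVM cross-validated
    classification, and the group-level evaluation statistics used in
    motor-imagery BCI reports. Results are tidy tibbles with broom-style
    tidy() and glance() methods and ggplot2 autoplot() methods.
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
    generics,
    ggplot2,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
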