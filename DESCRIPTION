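Package: ctinterplay
Title: Helical CT-Respiratory Motion Interplay Simulation and PTV Margins
    for Thoracic SBRT Image Guidance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the interplay between helical CT table translation and
    periodic longitudinal tumor motion during CT-on-rail image guidance for
    thoracic stereotactic body radiation therapy (SBRT). Provides breathing
    waveform models (sinusoid and exhale-weighted cos^2n profiles), a 1-D
    helical acquisition simulator that measures the longitudinal alignment
    error of a moving spherical target against its time-average position,
    systematic/random uncertainty summaries, PTV margin recipes (a quadrature
    margin formula and the linear van Herk form), Welch two-sample protocol
    comparisons from raw samples or summary statistics, encodings of clinical
    image-guidance decision rules (modality selection and bone-vs-GTV
    stability checks), and synthetic-data generators for phantom alignment
    datasets and patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
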