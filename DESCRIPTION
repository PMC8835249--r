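Package: starpa
Title: Tag-Guided Relative Protein Abundance from Immunoblot Densitometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements STARPA (simple tag-guided analysis of relative
    protein abundance), a calibration-based workflow for quantifying
    relative protein isoform levels from Western-blot densitometry.
    Tagged single-isoform lysate standards are diluted so that their
    anti-tag signals match a common reference; band densities of unknown
    samples are then expressed as molar ratios relative to the matched
    standard on the same blot, and antibody cross-reactivity between
    isoforms is estimated from the standards and removed, either by
    sequential subtraction or by solving the full linear crosstalk
    system. A synthetic immunoblot simulator with per-blot gain,
    lognormal measurement noise, optional signal saturation and a
    gel-image renderer provides ground-truth data for validating every
    stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png,
    withr
Config/testthat/edition: 3
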