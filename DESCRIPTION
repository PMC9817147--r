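Package: binlat
Title: Binaural Psychoacoustics: Adaptive Thresholds, Lateralization
    Metrics, and Normative Deviation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring and analysing binaural hearing with
    headphone psychoacoustics. Synthesises octave-band noise stimuli
    carrying interaural time or level differences, runs transformed
    up-down adaptive staircases for pure-tone audiometry and binaural
    tone-in-noise detection (including the binaural masking level
    difference, BMLD), computes a battery of lateralization variables
    from 9-key response logs, and compares individual listeners against
    mirror-augmented normative bands built from a control group.
    Includes parametric virtual listeners for end-to-end simulation of
    complete measurement sessions and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
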