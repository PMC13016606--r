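Package: kymotrace
Title: Kymograph Quantification of Motor-Protein Motility in TIRFM Time-Lapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and quantification tools for single-particle motility
    in live-cell total internal reflection fluorescence microscopy (TIRFM)
    time-lapses, modeled on kymograph workflows used to characterize
    dynein-dynactin transport. Provides a synthetic movie generator with
    per-fluorophore photobleaching, partial genetic labeling and camera noise;
    kymograph extraction along polyline paths at a configurable line width;
    automated ridge tracing with velocity, run-time, run-length and
    directional-switch measurement; region-in-region background-corrected
    intensity quantification with dimer-standard copy-number calibration; and
    randomization (permutation) statistics. Every stage is verifiable by
    parameter recovery against the simulator's ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
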