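Package: bagtraj
Title: Brain-Age Gap Trajectories Across Illness Duration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains Gaussian-process brain-age models on healthy-control
    feature tables (regional brain volume, cortical thickness, fractional
    anisotropy), applies linear age-bias correction, computes brain-age gaps,
    and compares patients against age- and sex-matched controls across
    illness-duration sliding windows using ANCOVA with partial eta squared.
    Includes a synthetic cohort generator with planted aging and
    duration-dependent deviation structure so the full pipeline is testable
    without access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, jsonlite
Suggests: testthat (>= 3.0.0), car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
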