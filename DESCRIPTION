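Package: fogcombine
Title: Combine Two-Rater Freezing-of-Gait Video Annotations
Version: 0.1.0
Authors@R: person("FOG", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministically combines the freezing-of-gait (FOG) video
    annotations of two independent raters into agreed FOG, agreed no-FOG and
    to-be-discussed segments, driven by a tolerance (seconds) and a correction
    (include/exclude) parameter. Reads and writes ELAN tab-delimited annotation
    exports, computes duration-weighted interrater agreement statistics
    (positive agreement, negative agreement, prevalence index, Cohen's kappa,
    ICC(2,1)), and ships a seeded simulator of imperfect rater annotations for
    fully self-contained testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
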