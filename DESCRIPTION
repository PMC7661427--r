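Package: advlfd
Title: Admissible Dissimilarity Values for Length-Frequency Subsampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a reduced length-frequency sample is
    still representative of the original sample. Implements robust mode and
    antimode detection under histogram bandwidth smoothing, a penalized
    L1 distance between empirical length-class CDFs, a deterministic
    iterative algorithm that constructs the minimal still-representative
    reference subsample and its admissible dissimilarity value (ADV),
    hierarchical (trip/haul/fish) sampling-effort reduction scenarios with
    nested random-effects mean-length summaries, and Monte Carlo machinery
    to validate the approach on normal-mixture length data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse,
    yaml
Config/testthat/edition: 3
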