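Package: emfreq
Title: Rank-Frequency Analysis of Emergency Admission Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the diagnosis mix of hospital emergency
    admissions. Builds per-year frequency tables of ICD-10 diagnosis
    categories (3-character level, capital-letter chapter groups with A and
    B merged), normalizes counts per 100,000 catchment inhabitants, ranks
    categories by multi-year mean with t-based 95% prediction intervals,
    fits competing exponential-decay and Pareto (power-law) models to the
    rank-frequency profile, and extracts the "vital few" high-volume
    diagnosis sets that cover a target share (80/20 analysis) of the case
    load for duty-roster competence planning. Includes a deterministic
    synthetic admission-stream generator with known ground-truth laws so
    the whole pipeline is testable without registry data.
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
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
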