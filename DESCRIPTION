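Package: radsafe
Title: Radial Nerve Safe-Zone Estimation from Bony-Landmark Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for landmark-normalized analysis of the radial nerve
    course on the posterior humerus. Reads and validates per-specimen
    cadaveric measurement tables, simulates seeded synthetic cohorts with
    sex-stratified arm-segment lengths and correlated nerve-crossing
    ratios, estimates intraobserver measurement precision (technical
    error of measurement, relative TEM and the coefficient of
    reliability), reproduces the cohort statistics (descriptive moments,
    Lilliefors normality testing with Monte-Carlo p-values, pooled-t
    group comparisons and the crossing-ratio regression), and computes
    absolute and relative surgical safe zones inside the Acromial
    Angle-Olecranon-Lateral Epicondyle triangle, with deterministic SVG
    rendering and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
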