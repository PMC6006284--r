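Package: prismcc
Title: Sufficient-Cause Interaction Tests for Case-Control Studies of
    Non-Rare Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests for sufficient-cause (mechanistic) interaction between
    two binary exposures in case-control studies where the disease is not
    rare.  Implements the prevalence-adjusted PRISM test, which combines
    the exposure-profile proportions observed among cases and controls
    with an external estimate of the overall disease prevalence (via
    Bayes' theorem) to recover absolute disease odds and log perils, and
    tests the log peril-ratio contrast with a delta-method Z-test.  Also
    provides three comparator tests (odds-scale PRISM, odds-scale RERI,
    and prevalence-adjusted risk-scale RERI), a parametric-bootstrap
    variance check, and a Monte Carlo framework for constructing
    constrained simulation scenarios and estimating type I error and
    power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
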