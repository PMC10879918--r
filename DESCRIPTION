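Package: isobmr
Title: Concentration-Time Benchmark Response Modelling for In Vitro
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives time-dependent benchmark concentrations (BMC) from
    concentration-by-time in vitro transcriptomics count data.  Genes are
    filtered, normalised to log2 counts per million, and screened for
    monotone concentration trends with a permutation-based two-sided
    Williams' trend test.  Each differentially expressed gene's 8x5
    concentration-time response is smoothed with a thin-plate spline, the
    collective response is modelled with a one-factor (principal component)
    model, and isobenchmark-response (isoBMR) contours are extracted from
    the common factor surface, from which a BMC at any exposure time is
    obtained by projection.  Includes a synthetic-data generator that
    emulates a 96-well plate concentration-time design with a known
    one-factor truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
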