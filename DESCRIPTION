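Package: semicorr
Title: Semi-Correlation Classification Models from SMILES Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary activity classifiers directly from SMILES strings
    using semi-correlations: least-squares regression of a 0/1 endpoint on an
    optimal descriptor assembled from correlation weights of SMILES attributes
    (single tokens and adjacent pairs and triples). Correlation weights are
    fitted by seeded Monte Carlo hill climbing under target functions with and
    without the index of ideality of correlation, which steers model quality
    towards the calibration set. Includes balanced four-way data splitting with
    Las Vegas split selection, an applicability domain based on statistical
    defects of attributes, promoter extraction across repeated optimization
    runs, a synthetic SMILES generator with planted attribute-activity rules
    for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
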