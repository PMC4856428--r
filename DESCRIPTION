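Package: ternflux
Title: Context-Specific Metabolic Network Reconstruction and FBA-Based
    Gene Essentiality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs context-specific genome-scale metabolic networks
    from ternary (high/medium/low) reaction-expression classifications using
    a fast iterative linear-programming algorithm guided by reduced costs,
    instead of the mixed-integer formulations common in this field. Includes
    flux balance and flux variability analysis, single-gene knockout
    essentiality analysis with a wild-type reference-flux skip rule,
    random-permutation essentiality backgrounds, and a one-sided two-sample
    Kolmogorov-Smirnov comparison against external gene-silencing
    essentiality scores. Models are read and written as SBML Level 3 with
    the fbc extension or a plain JSON dialect.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    xml2,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
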