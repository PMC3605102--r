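Package: examo
Title: Environment-Specific Metabolic Models from Gene Expression by
    Exploration of Alternative Metabolic Optima
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates discretized gene-expression measurements with
    genome-scale constraint-based models of metabolism to infer metabolic
    states in uncharacterized environments.  Solves the iMAT
    agreement-score mixed-integer program, systematically explores its
    alternative optima by reaction modulation to classify reactions into
    high-frequency (always active) and zero-frequency (always inactive)
    sets, extracts environment-specific models by greedy MBA-style
    pruning, predicts flux states by total-flux minimization with forced
    core activity, and predicts condition-specific essential genes by
    flux-balance single-gene deletion.  Includes a reaction-list CSV
    reader/writer, flux-variability dead-end trimming, a ten-reaction toy
    network, exhaustive small-network enumeration oracles, and a seeded
    synthetic-network generator for testing.  Mixed-integer programs are
    solved with the HiGHS solver through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9) on PATH
Config/testthat/edition: 3
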