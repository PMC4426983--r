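Package: vesiclefit
Title: Kinetic Modelling and Fitting of Hypertonic-Sucrose-Evoked
    Synaptic Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a minimal vesicle-state model of
    synaptic release evoked by hypertonic sucrose. A depot pool feeds a
    readily releasable pool (RRP) through priming and unpriming rate
    constants, and a time-dependent fusion rate constant with a
    Gompertz-type onset drains the RRP during the stimulus. Release
    rates are convolved with a canonical miniature EPSC to synthesize
    postsynaptic current traces, and recorded or synthetic traces are
    fitted by global plus local least squares to recover the rate
    constants and the RRP size. Fitted fusion rate constants are
    converted into activation-energy changes via the Arrhenius
    relation, including the allosteric calcium-sensor rate ladder, and
    nonparametric bootstrap summaries quantify parameter uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
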