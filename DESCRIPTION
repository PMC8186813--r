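Package: srnaevol
Title: Evolution of Small-RNA Amplification, Plasticity and Inheritance in
    Fluctuating Environments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how small-RNA (sRNA) production strategies
    evolve under environmental fluctuation. Implements the within-generation
    dynamics of sRNA levels (transcription, saturating template
    amplification, degradation), a cost-benefit fitness function of
    environmental matching, balanced cyclic environmental scenarios with a
    controlled switch count, strategy state updates for maternal sRNA
    transmission and plastic amplification rates in soma and germline, and
    evolutionary invasion analysis of mutant strategies against an optimally
    transcribing wildtype via geometric mean fitness and selection
    coefficients.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
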