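Package: stochimm
Title: Deterministic and Stochastic Models of Autoimmune T-Cell Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the onset and development of autoimmune
    disease through a five-compartment model of healthy host cells, naive,
    regulatory and autoreactive T cells, and a cytokine growth factor.
    Provides the deterministic ODE model with steady-state and stability
    analysis over cytokine-proliferation parameter grids; an exact Gillespie
    simulator of the equivalent continuous-time Markov chain; an Ito
    stochastic differential equation integrated by the Euler-Maruyama
    scheme, with ensemble summaries; the linear-noise approximation around
    stable steady states via the Lyapunov equation, including variance maps;
    oscillation and model-to-data comparison metrics; and a synthetic
    generator of per-eye CD4+ T-cell count series with the phenomenology of
    experimental autoimmune uveoretinitis (prodrome, infiltration peak,
    decaying oscillations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
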