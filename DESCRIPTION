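Package: thermokin
Title: Thermokinetic Modeling of Steady-State Metabolism and Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermokinetic modeling of metabolic networks coupled to
    transcriptional regulation, growth and a chemostat environment.
    Metabolite state is expressed through thermokinetic potentials derived
    from transformed Gibbs formation energies, reaction fluxes follow a
    linear force/resistance law, gene expression follows a phenomenological
    multiplicative Hill model, and steady states are found by damped Newton
    iteration after quasi-equilibrium (DAE) reduction. Includes a
    declarative plain-text model format, a packaged core model of
    Escherichia coli central carbon and energy metabolism across the
    aerobiosis scale, sweep and continuation drivers, overlay of relative
    measurement data, and assessment of production capabilities through
    enforced precursor drains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
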