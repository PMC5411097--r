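Package: crisprdyn
Title: Population Dynamics of CRISPR Adaptive Immunity in Bacteria-Phage
    Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic population-dynamics models of CRISPR-based
    adaptive immunity in well-mixed bacteria-phage cultures. Implements the
    single-spacer and N-spacer ordinary differential equation systems
    coupling wild-type, spacer-enhanced and infected bacteria with free
    phage, together with the analytic steady-state theory of host-virus
    coexistence: the fraction of unused carrying capacity, the critical
    spacer failure probability, the spacer to wild-type ratio, and the
    self-consistent mean-failure-probability solution for the steady-state
    spacer distribution. Provides a stiff-capable simulator with outcome
    classification (coexistence, phage extinction, bacterial extinction),
    scenario generators for the reference parameter regimes, diversity
    summaries (Shannon entropy, winner share) of spacer distributions, and a
    command-line interface driven by YAML/JSON configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
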