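Package: chemoswitch
Title: Logical Modeling and Dynamic Network Inference for the Trauma
    Chemokine Switch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying a putative chemokine-based control motif of
    systemic acute inflammation after blunt trauma. Provides a generic engine
    for multi-valued logical models with synchronous updates (rule grammar,
    three-level variables split into low/high bits, clamped-input simulation,
    exhaustive initial-state ensembles), the reference chemokine-switch model
    (injury -> X -> IP-10/MCP-1/MIG -> IL-6) together with a machine-checkable
    suite of behavioral constraints, state-transition-graph and attractor
    analysis with pseudo-Kaplan-Meier time-to-steady-state curves, an
    uncertainty search over logical rulesets consistent with a fixed network
    topology, a synthetic trauma-cohort generator emulating a clinical
    inflammatory-mediator panel, and first-order dynamic Bayesian network
    structure learning with the BGe score and Metropolis-Hastings structure
    sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
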