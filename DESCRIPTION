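Package: beliefsim
Title: Agent-Based Simulation of Interrelated Beliefs and Opinion Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulator of belief-system dynamics in
    which agents repeatedly exposed to news linking two concepts re-evaluate
    their attitudes to reduce cognitive dissonance or enjoy reassurance, and
    may adopt a dissonance-relieving new belief. Provides the elementary
    update rules (signed coherence, hierarchical change-probability gating,
    clamped attitude updates, new-belief adoption), a reproducible event
    loop, polarization metrics (extremity ratios, corner-cluster fractions,
    adoption ratio), CSV/JSON result serialization, configuration files and
    a command-line interface for single runs and replicate sweeps.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
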