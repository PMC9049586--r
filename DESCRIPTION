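Package: pkcycle
Title: Deterministic Kinetic Model of the Protein Kinase C Life Cycle
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mass-action kinetic model of the protein kinase C (PKC) life
    cycle: de novo synthesis, ordered constitutive phosphorylation by PDK1
    and mTORC2, autophosphorylation, second-messenger (DAG/PMA) activation,
    PHLPP-mediated dephosphorylation with degradation, and HSP70-mediated
    rescue. Provides a stiff ODE simulator with a square-pulse protocol
    engine (synthesis pulses, activator pulses, dephosphorylation blocking,
    PHLPP blocking, HSP70 overexpression), a registry of named stimulation
    scenarios, observable extraction (plateaus, half-times, per-pulse
    drops), local one-at-a-time parameter sensitivity analysis, and YAML
    run configurations with CSV/JSON result export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
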