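Package: dustdose
Title: Inhalation Dosimetry and Interspecies Extrapolation for Poorly
    Soluble Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimension-aware dosimetry calculations for granular
    biopersistent (poorly soluble, low-toxicity) dusts.  Implements the
    one-compartment constant-clearance model of alveolar lung burden,
    rat-to-human extrapolation of no-observed-adverse-effect
    concentrations (NOAECs) to human equivalent concentrations (HECs)
    under a retained-mass-per-alveolar-surface metric and a
    retained-volume-per-macrophage-pool metric, quarter-power allometric
    scaling of clearance half-times, a provenance-tagged registry of
    species physiology and tabulated MPPD deposition fractions, a
    dimensional-consistency audit of derived exposure values, and a
    sensitivity-grid engine with table rendering.  A synthetic scenario
    and noisy burden time-series generator supports property testing and
    clearance parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
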