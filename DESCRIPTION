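Package: protonQA
Title: Patient-Specific QA Toolkit for Spot-Scanning Proton Therapy
Version: 0.1.0
Authors@R: person("PSQA", "Maintainers", email = "psqa@example.org",
    role = c("aut", "cre"))
Description: An independent analytical pencil-beam dose engine for water
    phantoms (Bortfeld Bragg-curve model with simultaneous multi-energy
    fitting, double-Gaussian plus Cauchy-Lorentz lateral kernels), a
    gamma-index comparison cascade (2D, depth-searched "2.5D", and 3D) with
    clinical criteria and action levels, spot-delivery log-file deviation
    analytics with pattern-based periodic QA checks, and synthetic-data
    generators that produce plans, "measurements" and delivery logs with
    controlled ground truth for closed-loop verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
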