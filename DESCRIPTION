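Package: haemopost
Title: Haemodynamic Post-Processing for Aortic Dissection Flow Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing pipeline for time-resolved cardiovascular flow
    fields on tetrahedral meshes, oriented at type-B aortic dissection.
    Constructs the four standard inlet velocity profile variants (full
    three-component, flat, through-plane, velocity-scaled) from 4D-flow-MRI
    style inlet frames; derives aortic pressure targets from brachial cuff
    measurements and tunes three-element Windkessel outlet parameters with a
    0D lumped network; computes wall shear stress indices (TAWSS, OSI, RRT,
    ECAP), helicity metrics (helicity time series, local normalized helicity,
    bulk indices h1-h3 by subdomain and cycle phase), snapshot proper
    orthogonal decomposition with truncated reconstruction, and clinical
    correlates (transmural pressure, false lumen ejection fraction, luminal
    growth profiles, plane-wise Pearson correlation). Ships analytic
    synthetic-data generators (Womersley pipe flow, helical cylinder flow,
    a two-lumen dissection phantom) with closed-form ground truth so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
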