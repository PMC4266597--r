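Package: forcespec
Title: Single-Molecule Force Spectroscopy Analysis of Ultrastable
    Receptor-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for constant-speed atomic force microscope
    (AFM) pulling experiments on polyprotein-tethered receptor-ligand
    complexes. Provides freely rotating chain (QM-FRC) and worm-like chain
    polymer elasticity models, transformation of force-extension traces
    into contour-length space, cross-correlation assembly of barrier
    position histograms, fingerprint-domain classification with bond-history
    stratification, Bell-Evans rupture kinetics (analytic distributions,
    samplers, and dynamic force spectrum fits), and a kinetic Monte Carlo
    simulator of cantilever-PEG-polyprotein pulling experiments that
    produces force curves with ground-truth event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    pracma,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
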