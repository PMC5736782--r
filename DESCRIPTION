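Package: pgplung
Title: Pulmonary Disposition of P-Glycoprotein Substrates: Absorption
    Kinetics, Membrane Affinity and QSAR Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for studies of P-glycoprotein (P-gp) mediated
    pulmonary drug disposition in the isolated perfused mouse lung.
    Converts recirculating-reservoir perfusate concentration series into
    serial-sampling-corrected cumulative absorption, fits a first-order
    one-compartment accumulating absorption model, and computes
    non-compartmental AUC and lung-retention mass balance.  Companion
    assay calculators cover immobilised artificial membrane (IAM)
    chromatography capacity factors, multilamellar liposome vesicle
    partitioning, Ussing-chamber apparent permeability with TEER quality
    control, and Michaelis-Menten ATPase kinetics.  A from-scratch
    orthogonal PLS discriminant analysis (OPLS-DA) classifier predicts
    P-gp-dependent pulmonary disposition from thirteen computed
    physico-chemical descriptors, with cross-validated Q2 and
    scores/loadings export.  Seeded synthetic-data generators emulate
    every assay design so the full chain is testable without laboratory
    data; the published compound tables ship as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
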