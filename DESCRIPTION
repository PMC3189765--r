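Package: qsar3d
Title: Field-Based 3D-QSAR and Common-Feature Pharmacophore Modelling for
    Congeneric Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based three-dimensional quantitative
    structure-activity relationship (3D-QSAR) analysis of congeneric small
    molecule series: scaffold-based rigid alignment, comparative molecular
    field analysis (CoMFA, Lennard-Jones and Coulomb probe energies on a
    lattice) and comparative molecular similarity index analysis (CoMSIA,
    Gaussian similarity indices for steric, electrostatic, hydrophobic and
    hydrogen-bond properties), partial least squares regression by NIPALS
    with leave-one-out cross-validation and external test-set validation,
    stdev*coeff contour map extraction, and DISCO-style common-feature
    pharmacophore search over conformer ensembles.  Includes a synthetic
    congeneric-series generator with planted field coefficients so that the
    whole pipeline can be exercised and benchmarked without proprietary
    software or data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
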