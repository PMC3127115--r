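Package: grnncorr
Title: GRNN Correction of Calculated Homolysis Bond Dissociation Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-hoc statistical correction of density-functional-theory
    homolysis bond dissociation energies (BDE) of Y-NO bonds (Y = C, N, O, S)
    from quantum-chemistry-derived molecular descriptors. Descriptors are
    ranked and selected by grey relational analysis against the experimental
    reference series, decorrelated by correlation-matrix principal component
    analysis, and fed to a generalized regression neural network (a
    Gaussian-kernel memory-based regressor) that maps calculated toward
    experimental BDE. Ships a curated 92-molecule NO-carrier benchmark with
    experimental homolysis BDEs and twelve B3LYP/6-31G(d) descriptors, a
    synthetic descriptor-table generator with controlled correlation
    structure, and reporting of root-mean-square errors by data split.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
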