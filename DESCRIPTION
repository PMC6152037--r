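Package: thermgroups
Title: Atom-Group Additivity Models for Phase-Change Thermodynamics of
    Organic Molecules
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts five thermodynamic descriptors of organic molecules at
    298.15 K by atom-centered group additivity: the standard enthalpies of
    vaporization, sublimation and solvation (kJ/mol), the entropy of fusion
    and the total phase-change entropy of liquid crystals (J/mol/K). The
    enthalpy of fusion is derived as the difference between sublimation and
    vaporization enthalpies. Molecules are read from MDL SDF (V2000) files or
    SMILES strings, decomposed into atom-centered groups and whole-molecule
    special groups, and scored against packaged group-contribution parameter
    tables. The training side is also implemented: Gauss-Seidel least-squares
    evaluation of group contributions with valid-group gating, iterative
    outlier removal and 10-fold cross-validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR
Suggests:
    ChemmineOB,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chemgraph.R'
    'paramtables.R'
    'grouptyper.R'
    'predictor.R'
    'fitter.R'
    'fixtures.R'
    'thermgroups-package.R'
    'validation.R'
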