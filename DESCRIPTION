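Package: ScaffoldSpace
Title: Automated Substituent Placement on 3D Molecular Scaffolds
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Explores the local chemical space of 3D molecular scaffolds,
    including transition-metal complexes, by automated placement of
    substituent groups on user-chosen sites. Substituents are oriented with
    rotation matrices from a centroid-vector convention, bonded at
    covalent-radius distances, and relieved of steric strain by constrained
    relaxation that keeps the original skeleton frozen. Includes MDL Molfile
    (V2000) and XYZ readers/writers with covalent-radius bond perception,
    Kabsch and quaternion superposition with heavy-atom RMSD, serial
    error-propagation trend fitting, reaction-energy bookkeeping,
    Coulomb-matrix descriptors, and a gradient-boosted HOMO-LUMO gap
    regression harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'elements.R'
    'AllClasses.R'
    'AllGenerics.R'
    'structure-io.R'
    'substituent-library.R'
    'functionalize.R'
    'relax.R'
    'align.R'
    'metrics.R'
    'energies.R'
    'descriptors.R'
    'fixtures.R'
    'ScaffoldSpace-package.R'
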