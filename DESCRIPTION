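Package: allokin
Title: Virtual Screening Filters and Kinase Assay Analytics for Allosteric Inhibitor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a compound-selection and
    screening-analytics pipeline for discovering allosteric inhibitors of the
    IGF1R receptor tyrosine kinase. Provides target-arm triage of compound
    libraries (strong hydrogen-bond-donor SMARTS, aromatic-ring and
    hydrogen-acceptor prerequisites, toxicophore and logP/logS property
    filters), four-feature pharmacophore matching with torsion-grid conformer
    enumeration and a forbidden-volume rule, post-docking protein-ligand
    interaction filters (Val1063 hydrogen bond, Met1054/Met1079 sulfur-aromatic
    stacking, electrostatic and secondary hydrogen-bond rules), ligand-arm
    Markush substructure selection, 384-well plate statistics with Z'-factor QC
    and 3-SD hit calling, constrained sigmoidal IC50 fitting with selectivity
    ratios, and Michaelis-Menten / Lineweaver-Burk inhibition-mechanism
    classification. Seeded synthetic-data generators emulate every input so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    bio3d,
    graphics,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
SystemRequirements: OpenBabel command-line tool (obabel) on the PATH for
    SMILES/SDF/MOL2 interconversion; python with RDKit on the PATH for
    deterministic 3-D conformer embedding.
RoxygenNote: 7.3.3
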