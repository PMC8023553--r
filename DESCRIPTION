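Package: mpdimer
Title: Per-Residue Featurization of Membrane-Protein Dimer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts dimeric membrane-protein structures in PDB format
    (optionally with per-chain PSSMs) into per-residue feature tables:
    surface/interface classification from monomer relative solvent
    accessibility and interchain distances, accessible-surface-area
    descriptors (Shrake-Rupley sampling, Gly-X-Gly normalization),
    Jensen-Shannon-divergence conservation scores against selectable
    background distributions, B-factors, and seven classes of
    intermolecular interactions (close and hydrophobic contacts, hydrogen
    bonds, salt bridges, pi-pi stacking, T-stacking, cation-pi). Includes
    class-propensity correction, descriptive statistics with
    Kyte-Doolittle ordering, group tests, a synthetic-fixture generator
    with analytically known geometry, and a batch pipeline with a
    command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
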