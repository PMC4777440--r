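Package: allofep
Title: Allosteric Free Energy Profiles from Elastic Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based statistical-mechanical estimation of allosteric
    free energy. From a single protein structure, a C-alpha elastic network
    with distance-dependent force constants describes the ligand-free system;
    ligand binding is modelled by harmonically stiffening all residue pairs of
    a binding site. Low-frequency normal modes of the free and bound systems
    feed a per-residue allosteric potential whose partition functions yield
    per-residue, per-site and whole-protein configurational free energy
    changes, including the modulation free energy of sequential binding
    (cooperativity). Includes deterministic toy-structure generators and
    independent brute-force oracles for testing, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'allostery.R'
    'binding-sites.R'
    'chain-groups.R'
    'enm.R'
    'fixtures.R'
    'modes.R'
    'oracles.R'
    'output.R'
    'pipeline.R'
    'read-structure.R'
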