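Package: ringswap
Title: Construction and Validation of Domain-Swapped Doughnut-Like Protein
    Oligomer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds cyclic (Cn-symmetric) ring assemblies of a protein
    monomer, applies intermolecular domain-swap rewiring between neighbouring
    subunits, measures doughnut geometry (outer diameter, cavity diameter,
    ring width, height, radius of gyration) and filters candidate models
    against dimension ranges derived from transmission electron microscopy,
    atomic force microscopy and small-angle X-ray scattering. Includes Debye
    scattering curves for bead models, Guinier fitting with an iterative
    s*Rg window rule, Kabsch superposition and RMSD trajectory series,
    TM-score, hydrogen-bond occupancy analysis, Kabsch-Sander secondary
    structure assignment, and seeded synthetic-structure generators for
    validation. Developed around the doughnut-like oligomers formed by
    disulfide-stabilized human cystatin C.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'structures-io.R'
    'backbone-build.R'
    'ring-builder.R'
    'domain-swap.R'
    'geometry.R'
    'saxs.R'
    'superpose.R'
    'secondary-structure.R'
    'traj-metrics.R'
    'synthetic-data.R'
    'pipeline.R'
    'ringswap-package.R'
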