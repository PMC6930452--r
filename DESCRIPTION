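Package: oildrop
Title: Fuzzy-Oil-Drop Analysis of Hydrophobic Core Organization in Globular Proteins and Amyloid Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the fuzzy-oil-drop (FOD) model of hydrophobicity
    organization in protein structures. Residues are reduced to effective
    atoms and four per-residue hydrophobicity distributions are compared:
    theoretical (T, a 3D or 2D Gaussian fitted to the structure), observed
    (O, summed pairwise hydrophobic interactions within a cutoff), intrinsic
    (H, an amino-acid scale) and uniform (R). Kullback-Leibler divergences
    between these distributions are combined into relative-distance (RD)
    statistics that separate globular "spherical micelle" proteins
    (centralized hydrophobic core, RD < 0.5) from amyloid "ribbon-like
    micelle" fibrils (axial hydrophobic band, RD > 0.5 under a 3D Gaussian).
    Supports multi-level analysis of chains, protofibrils, superfibrils and
    inter-protofibril interfaces, discordant-residue elimination, residue
    category mapping, and a synthetic-structure generator (globules, fibrils,
    scrambled nulls) for ground-truth validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
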