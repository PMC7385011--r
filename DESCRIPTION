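Package: clefscope
Title: Structural Dynamics and Groove Geometry of Multi-Domain Glycoside
    Hydrolases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative structural-dynamics analysis of
    multi-domain carbohydrate-active enzymes, built around plant class C
    glycoside hydrolase family 9 (GH9) endoglucanases that carry a linker
    and a CBM49 carbohydrate-binding module. Provides C-alpha PDB and
    multiple-sequence-alignment handling with domain annotation, Kabsch
    ensemble superposition, iterative invariant-core detection from
    per-column ellipsoid volumes, anisotropic elastic-network normal-mode
    analysis with mode- and ensemble-derived residue fluctuations and
    dynamic cross-correlation maps, correlated-segment and interaction
    surface delineation with Shrake-Rupley buried areas, coordinate PCA
    with quadrant clustering of structure families, grid flood-fill
    groove/cavity measurement with a cylinder-approximation model of
    substrate-binding clefts, active-site residue set algebra with
    amino-acid class composition, and seeded synthetic multi-domain
    structure, ensemble and family generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
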