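Package: ctpop
Title: Cell-Type Populations for Spatially Registered Tissue Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct anatomical-structure cell-type populations from
    spatially registered single-cell datasets. Provides triangle-mesh and
    cuboid geometry primitives with a voxel brute-force oracle, bounding-box
    and mesh-based collision detection between cuboid tissue-extraction
    sites and 3D anatomical-structure meshes, corridors of plausible tissue
    origin via a filter-search algorithm, cell-type population construction
    with ontology crosswalking, marker-gene ranking and QC summaries, and an
    end-to-end pipeline that gates datasets by quality criteria and
    aggregates populations to extraction sites and anatomical structures,
    weighted by intersection percentage. A deterministic synthetic-data
    generator makes every step testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
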