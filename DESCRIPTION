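Package: TopoEvolve
Title: Evolutionary Design of Micro-Topography Surface Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic-algorithm design engine for libraries of cell-instructive
    surface micro-topographies. Topographical features are encoded as genes in
    two representations, a 200x200 binary pixel raster and an ordered list of
    geometric primitives (triangles, circles, lines). High-fitness parents
    (ranked by alkaline phosphatase staining intensity from a stem-cell
    screen) are bred with a registry of crossover and mutation operators under
    seven selection algorithms (Roulette, Random, Tournament, NSGA-II, Best,
    Worst, SPEA2), filtered for diversity by Pearson correlation of flattened
    rasters, screened for a 4 micron minimum pillar diameter, and assembled
    into a second-generation topography chip layout with flat and simple
    control surfaces. Library characterization includes eigenimage principal
    component analysis, pixel-occupancy maps, t-SNE embedding, and
    parent/progeny lineage accounting. A synthetic seed module emulates the
    first-generation design pool and its fitness screen so the whole pipeline
    is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    EBImage,
    igraph,
    png
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, ExperimentalDesign
RoxygenNote: 7.3.3
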