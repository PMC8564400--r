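Package: hexconnectome
Title: Connectome Reconstruction and Graph Analysis for Micropatterned
    Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing and quantifying directed synaptic
    networks of neurons cultured on honeycomb micropatterns. Models the
    hexagonal pattern lattice in closed form, simulates synthetic circuits
    whose occupancy statistics emulate published culture data (soma placement,
    receptive pattern areas, axon coverage), registers pattern arrays in
    raster images by FFT rotation estimation and normalized template
    cross-correlation, infers the directed connectome from axon-dendrite
    co-occupancy of patterns, computes degree, eccentricity, closeness and
    betweenness centrality with hub-role classification, and performs a
    13-class three-node motif census. Exports Cytoscape-compatible edge
    tables, SIF and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
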