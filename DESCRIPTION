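Package: graphtow
Title: Tug-of-War Games and Nonlocal PDEs on Weighted Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlocal difference operators (upwind gradients, 2-, infinity- and
    game p-Laplacians, morphological dilation/erosion/mean) on finite weighted
    graphs, together with three solver families built on them: an
    (alpha, beta, gamma)-parameterized averaging iteration for elliptic and
    parabolic interpolation problems (image inpainting, scribble-based
    colorization of images and point clouds), a monotone Dijkstra-like solver
    for the graph eikonal equation with multi-label front propagation
    (superpixels, segmentation, semi-supervised classification), and a
    Monte-Carlo Tug-of-War game simulator whose dynamic-programming value
    provides a stochastic cross-check of the deterministic solvers. Includes
    graph construction from images, point clouds and feature tables
    (grid, k-NN, epsilon-ball, region-adjacency), similarity weighting with
    patches, synthetic fixture generators, and end-to-end pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
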