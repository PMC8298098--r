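Package: olfconn
Title: Information-Flow Layers, Polarity and Stereotypy Analysis for
    Connectome Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing neuron-level connectome data of the insect
    olfactory system: probabilistic graph-traversal assignment of sensory
    layers, entropy-based axon-dendrite and class segregation scores,
    glomerular innervation-breadth and co-innervation permutation tests
    with Holm-Sidak correction, kernel-density voxel reconstruction of
    glomerulus volumes, and across-dataset morphological cell-type
    clustering with minimum-cut refinement. Ships a synthetic connectome
    generator with known ground truth (layers, cell types, planted
    co-innervation and polarity) so every analysis can be validated
    end-to-end without access to electron-microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
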