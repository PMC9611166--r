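Package: cocrystalgcn
Title: Graph Convolutional Prediction of Pharmaceutical Cocrystal Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether an active pharmaceutical ingredient (API) and a
    coformer will form a cocrystal from a paired molecular graph with separate
    covalent and noncovalent block adjacency matrices. Provides the CocrystalGCN
    classifier (node embedding, covalent and noncovalent graph convolutions with
    residual connections, sum pooling, fully connected head), dataset
    construction utilities (negative-pair generation, frequency-difference
    rebalancing with MaxMin diversity selection, stratified splits and k-fold
    cross-validation), layer-wise relevance propagation for per-atom
    attributions with 2-D heat maps, a coformer virtual-screening workflow, and
    a synthetic molecule-pair generator with a planted hydrogen-bond
    donor/acceptor pairing rule for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
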