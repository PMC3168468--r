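Package: ensembledyn
Title: Comparative Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing conformational ensembles of homologous
    proteins sampled by molecular dynamics: per-residue surrounding
    hydrophobicity, geometric hydrogen-bond persistence, essential dynamics
    (covariance/PCA of C-alpha fluctuations) with anisotropic U-tensors and
    sampling-quality indices, windowed dynamic cross-correlation networks,
    and salt-bridge networks with classifier-derived persistence cutoffs and
    spatial-proximity clustering.  Includes synthetic-ensemble generators
    with analytic ground truth for validating every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    e1071,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
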