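Package: gradmap
Title: Macroscale Gradient Mapping for Connectomes and Surface Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification, alignment and statistical evaluation of
    macroscale gradients from regional feature or connectivity matrices.
    Builds sparse, kernel-based affinity matrices (Gaussian, cosine,
    normalized angle, Pearson, Spearman), extracts low-dimensional
    gradients with principal component analysis, Laplacian eigenmaps or
    diffusion maps, aligns gradient sets across datasets with Procrustes
    analysis (pairwise and generalized) or joint spectral embedding, and
    tests gradient-map associations against spatial-autocorrelation
    preserving null models (spin permutations on spherical meshes and
    Moran spectral randomization). Includes readers and writers for
    delimited matrices, MatrixMarket, ASCII PLY and GIFTI surfaces, a
    deterministic synthetic-data module (planted-manifold connectomes,
    icospheres, smooth surface fields), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
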