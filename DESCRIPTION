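Package: specBLUP
Title: Multi-Kernel GBLUP with Hyperspectral Reflectance Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-environment genomic prediction for plant breeding trials in
    which genetic main effects are modeled with genomic (VanRaden) or pedigree
    (numerator) relationship matrices and genotype-by-environment interactions
    with relationship matrices derived from aerial hyperspectral canopy
    reflectance. Implements the full stage-wise pipeline: plot-level mixed
    models for trait and per-band BLUEs/BLUPs in alpha-lattice designs,
    developmental growth-stage classification of phenotyping time-points,
    kernel construction and record-level expansion (main, Hadamard G-by-E, and
    block-diagonal spectral kernels), multi-kernel GBLUP fitted by an
    eigenbasis Gibbs sampler or EM-REML, train-test partition schemes across
    site-years, breeding cycles and managed treatments, and a synthetic trial
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
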