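Package: rnadistgen
Title: Generative Modelling of RNA Tertiary Structure via Discrete
    Distance Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for de novo generation of RNA 3D structural ensembles.
    RNA structures are reduced to an 8-slot per-residue atom representation
    and encoded as L x L x 64 inter-atom distance tensors, which a vector
    quantised autoencoder (VQ-VAE) compresses into discrete per-pixel
    distance classes.  A masked autoregressive convolutional generator
    predicts class probabilities conditional on sequence, partially revealed
    classes, homologous sequence alignments and SHAPE reactivities.  A Monte
    Carlo tree search with an entropy-reduction value function samples
    autoregressive orderings and collects terminal states as a structural
    ensemble, which a pairwise discriminative score model ranks.  The package
    includes the full data-engineering layer (structure filtering, similarity
    clustering, leakage-free splits, cropping with contact flags, simulated
    and rescaled SHAPE), a synthetic-structure fixture generator, and an
    adapter that emits a coarse-grained refinement protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
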