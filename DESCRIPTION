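Package: scarmap
Title: Adversarial Reference Mapping and Label Transfer for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("scarmap", "developers", email = "scarmap@example.org", role = c("aut", "cre"))
Description: Supervised adversarial integration of partially overlapping
    single-cell RNA-seq reference and query datasets. A shared feature
    extractor, a cell-type predictor and one domain discriminator per
    reference cell type are trained jointly through a gradient-reversal
    layer; per-type and per-cell weights derived from the predictor's
    softmax dynamically down-weight interfering (non-shared) cell types
    and low-confidence cells, so only shared populations are aligned
    across batches. The package transfers high-resolution labels to
    query cells with a per-cell confidence score and an "unknown" call,
    implements bespoke evaluation metrics (over-correction score,
    adjusted Shannon diversity index, accuracy), and ships a seeded
    negative-binomial simulator of multi-batch atlases with shared and
    domain-specific cell types for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
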