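Package: cytofbatch
Title: Replicate-Based Removal of Batch Effects from Mass Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch-effect correction for multi-batch mass cytometry (CyTOF)
    studies using replicate-based removal of unwanted variation (RUV-III).
    Cells from reference samples replicated across batches are clustered
    with a self-organizing map and treated as pseudo-replicates; a low-rank
    unwanted-variation component is estimated from their residuals by
    singular value decomposition and subtracted from all cells, with every
    protein serving as a negative control. Includes FCS 3.0/3.1 input and
    FCS 3.1 output, a 95th-percentile scaling baseline, evaluation metrics
    (binned earth mover's distance, Hellinger distance on cluster
    proportions, batch and biology silhouette scores, cross-batch median
    differences), diagnostic summaries with a static HTML report, a
    synthetic multi-batch study generator with ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    MASS,
    Rtsne
Config/testthat/edition: 3
RoxygenNote: 7.3.3
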