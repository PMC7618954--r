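Package: spreadnet
Title: Spread of Association in Spiking Cell-Assembly Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent network of conductance-based leaky
    integrate-and-fire neurons with co-dependent excitatory and inhibitory
    synaptic plasticity, embeds ring-structured cell-assembly memories, and
    quantifies how reduced inhibition during learning produces a graded
    "spread of association" across the memory map. Also provides the
    companion behavioural statistics for ring-structured association tasks
    (overgeneralisation errors, mean rank proximity, topological distance,
    Bang's blinding index) with permutation and bias-corrected bootstrap
    inference, a pupillometry preprocessing and cluster-based permutation
    pipeline, and synthetic-data generators with known ground truth for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
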