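Package: transductr
Title: Single-Molecule Detection of Phage-Mediated DNA Packaging from Long Virome Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule "transductomics": detecting discrete
    packaged-DNA length peaks in long-read virome data, quantifying
    virus-like-particle (VLP) enrichment of bacterial scaffolds, and
    classifying bacterial-DNA packaging events into prophage induction,
    generalised transduction, specialised transduction, lateral transduction
    and gene-transfer-agent-like packaging. Includes a synthetic encapsidated
    DNA read simulator covering cos, headful, Mu-like, generalised,
    specialised and lateral transduction as well as GTA packaging mechanisms,
    with free-DNA contamination and post-packaging degradation models, so
    every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
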