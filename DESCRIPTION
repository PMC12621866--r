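Package: foldcensus
Title: Characterizing the Sequence and Structure Output of Generative Protein Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for auditing the output of generative protein
    language models: generic decoding engines (temperature, top-k, nucleus
    sampling, repetition penalty) over pluggable token-probability models,
    left-to-right Gibbs sampling for masked models, an abundance-weighted
    background sequence sampler, sequence validity and composition filters,
    consensus SCOP fold assignment from structure-search hit tables,
    sequence-escape statistics from homology hits, Shrake-Rupley solvent
    accessible surface area and burial/coil fractions, and hyperparameter-scan
    summaries. Synthetic-data generators with planted ground truth make every
    stage testable without GPU inference or external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
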