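Package: clonesim
Title: Simulation of Single-Cell Copy Number Profiles and Sequencing Reads
    from Tumor Cell Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates single-cell whole-genome copy number data from tumors.
    Cell genealogies are drawn under the neutral coalescent with exponential
    growth and optional selective sweeps, diluted with normal and
    pseudo-normal cells, and partitioned into subclones. Two-allele genomes
    evolve along the tree by multi-scale copy number events (focal gain,
    loss and copy-neutral LOH, chromosome-arm and whole-chromosome events,
    and whole-genome duplication) with full allele-lineage tracking. Outputs
    include ground-truth and error-injected binned copy number profiles
    (segment-boundary noise and state-proportional jitter) and
    haplotype-aware paired-end sequencing reads with a smooth, tunable
    per-window coverage landscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
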