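Package: wormlegacy
Title: Transgenerational Longevity Analytics for Lifespan, H3-Normalized
    ChIP-seq, Candidate-Gene Integration and Radial Fluorescence Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative analyses
    used in transgenerational-longevity studies of C. elegans:
    replicate-structured lifespan statistics (Kaplan-Meier curves,
    per-replicate log-rank tests combined with Fisher's method, and percent
    mean-lifespan-extension summaries), H3-normalized histone-mark ChIP-seq
    profiling (TSS-centered signal matrices, metaprofiles, and windowed
    differential-site calling with Benjamini-Hochberg correction), a
    candidate-gene integration funnel (differential sites mapped to genes,
    two-mark intersection, transcriptional up-regulation filtering, promoter
    extraction and position-weight-matrix motif scanning), and radial
    fluorescence-intensity profiling of cells from the nuclear center to the
    cell periphery with normalized-radius binning and per-bin group
    statistics. Seeded synthetic-data generators with machine-readable
    ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    car,
    dplyr,
    EBImage,
    flexsurv,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
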