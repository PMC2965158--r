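Package: trftax
Title: Terminal Restriction Fragment Size Prediction and Taxonomic
    Labeling of T-RFLP Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts terminal restriction fragment (T-RF) sizes of
    full-length or 5'-truncated 16S rRNA gene sequences for a given
    fluorescently labeled primer and restriction enzyme set, using
    closest full-length reference sequences to bridge the unsequenced
    5' gap of partial clones. Provides IUPAC-aware fuzzy primer search,
    in silico restriction digestion on the labeled strand, k-mer seeded
    nearest-reference retrieval with Smith-Waterman re-ranking,
    taxonomic binning via reference lineages, matching of predictions
    to observed chromatogram peak tables with multi-enzyme consensus,
    and a reproducible synthetic community fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
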