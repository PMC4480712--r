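Package: svhotspot
Title: Structural-Variant Hotspot Analysis from Mate-Pair Sequencing and Array Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for rearrangement hotspots such as
    the TP53 intron 1 breakpoint cluster in osteosarcoma. Generates synthetic
    reference genomes, plants structural variants (deletions, inversions,
    reciprocal translocations, inverted insertions) with explicit junction
    mechanics, and simulates long-fragment mate-pair (DNA paired-end tag)
    libraries with truth records. Calls structural variants from discordant
    read-pair clusters, performs targeted-capture one-end-anchored breakpoint
    discovery, characterizes junction sequences (micro-homology, untemplated
    insertion, junctional duplication, net loss), segments copy-number probe
    tracks and classifies transitions inside a gene window, detects copy-neutral
    loss of heterozygosity from B-allele fractions, and reports hotspot
    recurrence, in-silico break-apart FISH results, cohort frequencies and
    delta-delta-Cq fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
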