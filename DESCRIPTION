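Package: dinuscape
Title: Dinucleotide Structural DNA Property Landscapes Around Genomic Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds fixed-resolution genomic maps of dinucleotide, tandem-repeat and
    annotation content, converts them into structural DNA property tracks (Roll, Twist,
    Slide and related dinucleotide step models), and analyses how those properties behave
    around functional annotations such as CTCF binding sites, promoters and TAD borders.
    Includes zero- and first-order Markov null models for dinucleotide and tandem-repeat
    content, anchor-centered environment profiles with interior masking, baseline-expansion
    central peak calling, bootstrap map correlation with a shuffled null, and a linear
    decomposition of property peaks into per-dinucleotide and per-repeat-class influences.
    A synthetic-genome generator with programmable repeat insertions and anchor-flank
    dinucleotide enrichment provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
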