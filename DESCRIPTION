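Package: DGRtools
Title: Detection and Hypermutation Analysis of Diversity-Generating
    Retroelements in Phage Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates diversity-generating retroelement (DGR) cassettes in
    phage and prophage genomes and quantifies the adenine-specific
    hypermutation that distinguishes their template repeat (TR) from the
    variable repeats (VR) embedded in target genes. Repeat pairs are found
    with a seed-and-extend scan under an asymmetric mismatch model in which
    substitutions at template adenines are expected and all other mismatches
    are penalised; detected pairs are assembled with ORF annotations into
    cassettes that may carry more than one target gene. Substitution spectra
    are reported at nucleotide, codon and amino-acid level, including the
    repertoire of residues reachable from adenine-rich codons, AAC/AAT
    codon-position bias, and physicochemical category spectra. A
    conservation-profile builder and scanner support signature analysis of
    the conserved C-terminal Ig-like anchor domain of tentaclin-family
    receptor-binding proteins, and a forward simulator of DGR retrohoming
    produces genomes with ground-truth mutation records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Sequencing, Alignment, ComparativeGenomics, Genetics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
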