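Package: aludel
Title: Alu-Mediated Deletion Discovery, Junction Mapping and Diagnostic PCR Design
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterising large genomic deletions mediated by
    recombination between interspersed repeats. Parses RepeatMasker-style
    repeat annotation, summarises the repeat landscape of a locus and
    nominates same-family same-orientation repeat pairs as deletion
    substrates; maps deletion breakpoints and microhomology from a junction
    (mutant) sequence against the wild-type reference with HGVS-conformant
    3'-normalisation; predicts PCR products of primer panels on wild-type and
    deleted alleles and implements a two-reaction presence/absence genotype
    call; performs homozygosity and founder-haplotype analysis over
    microsatellite genotypes in consanguineous pedigrees; and generates
    fully ground-truthed synthetic loci (repeat-laden reference, equal
    crossover deletion allele, junction amplicons, pedigree genotypes) so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: StructuralVariation, SequenceMatching, Genetics, Software
RoxygenNote: 7.3.3
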