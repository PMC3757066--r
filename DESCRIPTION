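Package: concestor
Title: Ancestral Reconstruction and Divergence Analysis of a Dimorphic Cis-Regulatory Element
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the ancestral ("concestor") sequence of a
    cis-regulatory element from aligned population alleles and outgroups by
    minimum-change parsimony over a rooted tree, catalogues derived point and
    indel mutations against each allele, annotates IUPAC consensus
    transcription-factor binding sites and calls their gain, loss or
    conservation, performs in-silico restriction digests for RFLP genotyping
    with Mendelian segregation testing, designs chimeric and
    mutation-substituted reporter constructs, and summarises reporter-activity
    and binding-titration measurements. A seeded synthetic-data generator
    reproduces the statistical structure of such a study (population alleles
    at ~98% identity, planted binding sites, F2 crosses, noisy replicate
    intensities) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
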