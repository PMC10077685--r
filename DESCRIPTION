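Package: mitostruct
Title: Comparative Structural Analysis of Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural analysis of circular fungal
    mitochondrial genomes at the population scale. Reads and writes annotated
    mitogenomes (GenBank flat file, FASTA plus annotation tables), normalizes
    rotation and strand, and computes composition statistics (AT content, GC
    skew). Detects inverted-repeat pairs and calls the orientation of the
    invertible segment between them; builds a registry of homologous intron
    insertion sites in spliced coordinates and maps each strain's introns onto
    it with type, subtype and anomaly calls; catalogs plasmid-derived DNA
    polymerase (dpo) gene fragments and summarizes their presence per clade;
    assigns strains to intron distribution pattern (IDP) classes and
    quantifies clade congruence; collapses SNP haplotypes and classifies
    variants by annotation region; and infers the minimum number of intron
    gain/loss events on a phylogeny under Dollo parsimony, merging
    simultaneous losses of neighboring introns into single block events. A
    seeded simulator of mitogenome structural evolution along a tree provides
    ground-truth data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
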