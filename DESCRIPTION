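Package: amoacap
Title: Probe-Capture Enrichment Simulation and OTU Analysis for amoA/CuMMO Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted-gene enrichment sequencing of ammonia
    monooxygenase subunit A (amoA) and other copper membrane monooxygenase
    (CuMMO) family genes. Builds curated reference databases, designs tiled
    100-mer capture probes with coverage reporting, constructs synthetic
    plasmid mock communities with closed-form expectations (insert base
    fraction, gene copies per nanogram, contained-fragment probability),
    simulates fragmentation, hybridisation capture, LM-PCR and paired-end or
    long-read amplicon sequencing, and runs a de-novo OTU workflow (quality
    control, read merging, greedy assembly, ORF extraction, protein homology
    filtering, chimera removal, 97 percent identity clustering) with
    RPKMS quantification, analytic rarefaction, taxonomy/ecotype assignment
    and neighbour-joining trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
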