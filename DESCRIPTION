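Package: scafmap
Title: Genetic-Map Guided Scaffold Anchoring, Pseudo-Chromosome Assembly
    and Bulked-Segregant QTL Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning per-population genetic linkage maps of an F1
    outcross (CP) population into a chromosome-level genome assembly and for
    locating trait loci by bulked-segregant sequencing. Implements the marker
    quality-control cascade used for genotyping-by-sequencing SNP data (depth
    masking, segregation chi-square test, missingness/integrity filters,
    per-scaffold redundancy reduction), weighted multi-map consensus building
    with collinearity-maximising scaffold ordering and orientation,
    pseudo-chromosome FASTA/AGP construction with assembly and map summary
    statistics, a |Delta(SNP-index)| sliding-window QTL-seq scan with
    top-quantile candidate intervals projected back onto scaffold pieces,
    reciprocal-best-hit synteny correlation between genomes, and a synthetic
    data generator (Kosambi-distance recombination, three CP marker classes,
    overdispersed read depths, phenotype-pooled bulks) so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
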