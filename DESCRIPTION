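Package: extremoseq
Title: Extreme-Phenotype Exome Cohort Selection, Variant Prioritization
    and Gene Burden Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for extreme-phenotype whole-exome studies of quantitative
    traits. Selects trait-extreme and normal groups from a phenotype table,
    computes the baseline comparison table with normality-gated test selection
    and the post hoc power of the group comparison, classifies variants into an
    ANNOVAR-style region and functional-class taxonomy, applies a prioritization
    cascade over deleteriousness predictions, population allele frequencies and
    site quality, collapses prioritized genotypes per gene into two-group
    wild/het/hom tables, and ranks genes by a carrier-rate ratio with an exact
    test. A synthetic-cohort generator with planted gene-level carrier
    enrichment makes every stage testable without access to raw sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
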