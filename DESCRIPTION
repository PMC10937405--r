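Package: svdosage
Title: Structural Variants as Bidirectional Dosage Regulators of Gene Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing structural variants (SVs) as dosage
    regulators of gene expression in plant pan-genomes and populations.
    Builds nonredundant SV catalogs from per-genome call sets, links SVs to
    their nearest genes, classifies SVs as expression-suppressing or
    expression-promoting from presence/absence genotype groups in both an
    assembly panel and a genotyped population, quantifies the regulatory
    signatures behind each direction (CpG-island density and weighted
    methylation for suppression, transcription-factor binding-site
    enrichment for promotion), classifies syntenic gene families into
    pan-genome classes with morphotype-specific loss and homoeolog
    retention analyses, and runs case-control Fisher-exact SV-GWAS with
    Bonferroni correction, haplotype grouping, LD summaries and cis/trans
    labelling. A synthetic-data module generates pan-genome panels and
    populations with planted effects so every stage can be validated
    against a known truth table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    minpack.lm,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: StructuralVariation, GeneExpression, GenomeWideAssociation,
    FunctionalGenomics, Epigenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SVCatalog-methods.R'
    'assoc.R'
    'catalog.R'
    'config.R'
    'dosage.R'
    'families.R'
    'io.R'
    'regsig.R'
    'simulate.R'
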