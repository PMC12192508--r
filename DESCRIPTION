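Package: mndkit
Title: Mitonuclear Discordance Analysis for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes mitonuclear discordance (MND) -- the fraction of an
    individual's nuclear ancestry calls at nuclear-encoded mitochondrial
    genes that do not match the continental ancestry of their mtDNA
    haplogroup -- from local-ancestry annotated VCFs (FLARE dialect),
    gene interval BED files and Haplogrep-style haplogroup tables.
    Provides gene-wise and gene-set-averaged MND, global ancestry from
    local-ancestry averages, intergenerational change in MND for
    mother-offspring pairs, cohort comparison statistics (ANOVA or
    Kruskal-Wallis omnibus tests, Bonferroni-corrected pairwise tests,
    Cohen's d effect sizes, variance tests, Spearman correlation), and a
    synthetic admixed-cohort simulator with known ground truth for
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    stats,
    tools,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
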