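Package: ssgxe
Title: Single-Step Reaction-Norm GWAS for Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R:
    person("ssgxe", "maintainers", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of
    genotype-by-environment interaction in livestock using a two-step
    reaction-norm single-step GBLUP. Builds pedigree (A), genomic (G,
    VanRaden method 1) and combined (H) relationship matrices, derives a
    standardized environmental gradient from contemporary-group BLUEs, fits
    random-regression (Legendre intercept/slope) mixed models with
    heterogeneous residual variances, estimates variance components by Gibbs
    sampling, back-solves genomic breeding values into SNP effects with
    iterative variance weighting (WssGWAS), partitions additive genetic
    variance into moving SNP windows, and summarizes G-by-E through SNP-effect
    reaction norms, GEBV correlations across environments and top-sire
    reranking. Includes a pedigree/genotype/phenotype simulator with known
    intercept and slope genetic (co)variances for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    coda,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
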