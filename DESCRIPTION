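Package: regflm
Title: Region-Based Association Tests for Family Data under Functional
    Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Region-based association analysis of quantitative traits in
    samples of related individuals using functional linear mixed models.
    Genotype dosages across a genomic region and their effects are smoothed
    with B-spline or Fourier bases inside a linear mixed model with a
    polygenic random effect whose covariance is proportional to the
    pedigree (or genomic) relationship matrix.  Provides maximum-likelihood
    fitting of the null polygenic model via eigendecomposition, F, likelihood
    ratio and score tests of the smoothed regional fixed effects with
    automatic reduction of the number of basis functions for small regions,
    pedigree kinship computation, readers for VCF/dosage-matrix, FAM
    pedigree and phenotype files, and a gene-dropping simulator of
    multi-family samples with LD-structured regional genotypes and polygenic
    traits for type I error and power experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    pracma,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
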