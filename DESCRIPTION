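Package: rnapopgen
Title: Reference-Free Population Genomics from RNA-Seq Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood SNP and genotype calling from read counts
    mapped to de novo assembled transcriptome contigs, without a reference
    genome and without base-quality information. A per-contig sequencing
    error rate is estimated jointly with per-site allele frequencies, and
    diploid genotypes are called from posterior probabilities under
    Hardy-Weinberg priors. A likelihood-ratio test with Dirichlet-multinomial
    (beta-binomial) overdispersion flags spurious SNPs created by hidden
    paralogy (distinct loci collapsed into one contig). Downstream tools
    compute synonymous and non-synonymous nucleotide diversity (piS, piN),
    heterozygote deficiency (FIS), fixed divergence to an outgroup (dS, dN),
    McDonald-Kreitman neutrality indices (NI, alpha, omega_a), and folded
    site-frequency spectra by hypergeometric projection with Tajima's D.
    A synthetic-data generator with known truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'counts-io.R'
    'genotyper.R'
    'vcf.R'
    'paralog.R'
    'orf-cleaning.R'
    'popgen-stats.R'
    'sfs.R'
    'simulate.R'
    'pipeline.R'
    'rnapopgen-package.R'
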