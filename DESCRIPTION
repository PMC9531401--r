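Package: kmertyper
Title: Alignment-Free Graph-Based Genotyping of Biallelic Variants from
    k-mer Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genotypes known biallelic SNPs and short indels directly from
    raw sequencing reads, without alignment. Variants are represented as
    allele nodes in an acyclic pangenome graph built from a reference
    genome and a phased haplotype panel; each allele is represented by
    k-mers chosen to minimise their expected population frequency.
    Observed k-mer counts are scored under a mixture-of-Poissons
    likelihood whose components reflect how often each panel individual's
    diploid genome contains the selected k-mers, which makes the model
    robust to duplicated (non-unique) k-mers. A single precomputed
    "helper" variant per site supplies a haplotype-panel prior, and
    posterior genotype probabilities are written as VCF. Includes a
    self-contained synthetic-data generator (reference with optional
    segmental duplications, mosaic haplotype panels with tunable linkage,
    diploid samples and error-carrying reads) so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: GenomicVariation, SNP, Genetics, Sequencing, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'helperVariants.R'
    'utils.R'
    'graph.R'
    'kmerIndex.R'
    'countModel.R'
    'archive.R'
    'io.R'
    'counting.R'
    'genotype.R'
    'kmertyper-package.R'
    'simulate.R'
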