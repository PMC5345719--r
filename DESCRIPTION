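Package: gbsf2
Title: Genotyping-by-Sequencing Post-Processing for Heterozygous F2 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for genotyping-by-sequencing (GBS) data
    from biparental F2 intercrosses. Provides parental-allele SNP filtering
    (triplicate-parent consistency, minor allele frequency, read-depth
    masking, physical thinning, per-site missingness), ABH genotype encoding
    with flank-based imputation and run-length error correction tuned to the
    long uniparental haplotype blocks of F2 populations, error-motif
    profiling, two-point EM genetic-map estimation with Haldane and Kosambi
    map functions, single-QTL interval mapping by multiple imputation with
    permutation thresholds and Bayes credible intervals, an F2/GBS simulator
    for power studies, and in-silico restriction digests for enzyme choice.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    vcfR,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
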