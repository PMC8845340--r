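Package: phasebench
Title: Pedigree-Based Evaluation of Haplotype Phasing Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark population-based haplotype phasing against a
    trio-derived gold standard. Builds "true" haplotypes from sequenced trios
    and duos with Mendelian segregation rules, scores any phased data set with
    switch-error counts and rates, quality-adjusted (QA) haplotype block
    lengths, QAN50 and pairwise SNP phasing accuracy, and applies
    pedigree-genetics quality control to variants (Hardy-Weinberg, offspring
    segregation, Mendelian-inconsistency and informativeness filters) and to
    genomic regions (chromosome ends, high-coverage windows,
    recombination-rate peaks with inheritance-vector correlation). Includes a
    seeded pedigree genotype simulator (Poisson crossovers over a genetic map,
    genotyping error, missingness, artifact variants, misplaced-marker blocks)
    so every stage can be exercised against known ground truth, and a
    crossover-count diagnostic of genotype data quality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
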