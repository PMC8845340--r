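# phasebench

Pedigree-based evaluation of haplotype phasing quality.

## What it is for

When a sequenced pedigree is available, the haplotypes of offspring with
genotyped parents can be resolved by Mendelian segregation rules — exactly,
wherever they are resolved, as long as the genotype data are clean. Those
family-derived haplotypes are a gold standard against which the output of
population-based phasing software (ShapeIT, Beagle, Eagle, FImpute,
AlphaPhase, ...) can be scored. `phasebench` implements the full
methodology for users who have such a pedigree (human or livestock) and
want to benchmark phasing on their own data:

- **Gold standard**: `phase_pedigree()` applies site-wise Mendelian rules
  to every trio (both parents genotyped) and duo (one parent), flagging
  Mendelian inconsistencies instead of phasing through them.
- **Metrics**: `evaluate_phasing()` compares any phased VCF to the gold
  standard over *informative sites* (heterozygous and phase-known in the
  truth). It reports phasing yield, switch error count SEC and rate
  SER = SEC / #informative markers, quality-adjusted (QA) haplotype block
  lengths (bp between successive switch errors x fraction of phased SNPs),
  QAN50 (the largest L such that 50% of informative SNPs lie in blocks
  with QA length >= L), the genome fraction in blocks above 1/5/10/50 Mb,
  and pairwise phasing accuracy by distance (probability of an even number
  of switches between two sites d apart).
- **Variant QC**: `apply_variant_filters()` keeps variants behaving like
  true Mendelian SNPs — Hardy-Weinberg p > 0.05, offspring segregation
  p > 0.05, at most one Mendelian inconsistency pedigree-wide, chance
  probability of zero inconsistencies < 1e-12, MAF >= 0.01, missingness
  <= 5% — then masks opposite homozygotes and re-checks as final edits.
- **Region QC**: `build_exclusion_mask()` unions 10-kb chromosome ends,
  high-coverage windows (> 6x the individual mean,
  `flag_high_coverage_regions()`), and putative map errors: small regions
  flanked by recombination-rate peaks (> 0.05) whose within-family
  segregation decorrelates from their neighbourhood (r² < 0.90,
  `flag_map_error_regions()`).
- **Crossover diagnostic**: `detect_crossovers()` + `co_summary()` count
  crossovers per parent-offspring meiosis; counts far above the genetic-map
  expectation (in Morgans) expose genotyping and marker-order errors.
- **Simulator**: `simulate_dataset()` generates a trio-rich pedigree
  (default 264 individuals, 98 trios) with Poisson recombination over a
  genetic map, genotyping error and missingness; `corrupt_haplotypes()`,
  `inject_artifact_variants()` and `inject_map_errors()` produce
  controlled long/point switches, non-Mendelian artifact variants and
  misplaced marker blocks, all logged, so every stage can be validated
  against ground truth.

I/O: VCF (GT field; `|` = phased) via vcfR, PLINK 6-column FAM, 4-column
genetic map text, BED for region masks and depth windows.

## Worked example

```r
library(phasebench)

out <- run_pipeline(list(
  seed = 1,
  distances_bp = c(1e6, 5e6, 1e7),
  sim = list(n_chrom = 3, chrom_bp_lengths = 1e8, chrom_cM_lengths = 100,
             n_variants_per_chrom = 2000),
  corruption = list(long_switch_rate_per_Mb = 0.02,
                    point_switch_rate_per_site = 1e-4,
                    unphase_fraction = 0.02)))
print(out$co_summary)
#> co_summary: 279 meioses
#>   mean crossovers/meiosis: 2.69
#>     female parents: 2.52
#>     male parents: 2.88
#>   expected: 3.00  inflation ratio: 0.90
head(out$eval$per_individual[, c("individual", "sec", "ser", "yield",
                                 "qan50")], 2)
#>   individual sec        ser     yield    qan50
#> 1       T001   8 0.01073826 0.9812081 36641680
#> 2       T002   9 0.01174935 0.9791123 59337404
```

The crossover diagnostic sits near the map expectation (3 Morgans
simulated; the ratio of 0.90 reflects crossovers lost where the strict
informativeness filter thins the marker panel, not genotyping error — on
the unfiltered panel it is 1.0), so the genotype data are clean. Each
validation individual then gets its switch-error, yield and QAN50 metrics
against the Mendelian gold standard — here measuring the configured
corruption: a median SEC of 6 from 0.02 long switches/Mb over 300 Mb plus
1e-4 point switches, at 98% yield from the 2% unphasing.

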