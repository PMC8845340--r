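---
title: "Evaluating haplotype phasing with a sequenced pedigree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating haplotype phasing with a sequenced pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasebench)
```

## The problem

Population-based phasing software reconstructs, for each individual, which
alleles travel together on the same homologous chromosome. In real data the
true haplotypes are unknown, so the accuracy of these reconstructions has to
be measured indirectly. When a sequenced pedigree is available there is a
better option: for an offspring whose parents are also genotyped, Mendelian
segregation rules pin down the parental origin of most alleles exactly. In
the absence of genotyping and marker-order errors these family-derived
haplotypes are *exact* wherever they are resolved, and they can serve as a
gold standard against which any population-phased data set is scored.

`phasebench` implements that whole methodology as a reusable pipeline:

1. a **gold standard** built from trios and duos by site-wise Mendelian
   rules (`phase_pedigree()`);
2. a **metric suite** — phasing yield, switch error count (SEC) and rate
   (SER), quality-adjusted (QA) haplotype block lengths, QAN50, genome
   fractions in long blocks, and pairwise phasing accuracy by distance
   (`evaluate_phasing()`);
3. **variant quality control** by pedigree-genetic rules — Hardy-Weinberg,
   offspring segregation, Mendelian-inconsistency counting, a
   chance-probability informativeness rule, MAF and missingness
   (`apply_variant_filters()`);
4. **region quality control** — chromosome-end trimming, high-coverage
   windows, and recombination-rate peaks cross-checked against
   within-family segregation patterns (`flag_map_error_regions()`,
   `build_exclusion_mask()`);
5. a **crossover-count diagnostic** (`detect_crossovers()`,
   `co_summary()`): per-meiosis crossover counts should match the genetic
   map length in Morgans; counts far above it reveal genotyping or
   marker-placement errors before any phasing is attempted;
6. a **seeded simulator** (`simulate_dataset()`, `corrupt_haplotypes()`,
   `inject_artifact_variants()`, `inject_map_errors()`) that provides
   ground truth for all of the above.

The data this methodology was designed around — a deeply sequenced
trio-rich livestock pedigree — is not publicly available, so the simulator
is a first-class component: every empirical claim the package makes is
demonstrated on synthetic data with a known truth.

## The gold standard and why it is site-wise

`phase_trio_site()` assigns the paternal and maternal allele of an offspring
at one site if and only if *every* parental transmission compatible with the
three genotypes agrees on it: homozygous children are trivially resolved;
heterozygous children are resolved when at least one parent's transmitted
allele is forced. Configurations with no compatible transmission (e.g.
opposite homozygotes) are flagged, never phased. No linkage or LD
information is used. This restraint is deliberate: linkage-based imputation
would phase more sites but would import inference error into the reference
itself, destroying the "exact where resolved" guarantee the evaluation
rests on. The price is that sites where both parents are heterozygous stay
unphased; they are simply not informative for the metrics.

Within a family, hapA is paternal and hapB maternal by convention. Both
members of an opposite-homozygote pair are masked when conflicts are
removed, because the data cannot say which side carries the error; for the
rarer impossible-trio configurations all three genotypes are masked so that
masking provably clears every recorded conflict.

## The metrics

All metrics are computed over **informative sites**: sites heterozygous and
phase-known in the gold standard whose genotype agrees with the evaluated
haplotypes. Sites with discordant or missing genotypes in the evaluated set
are excluded and reported separately — relative orientation is undefined
there. (The phasers this methodology targets preserve input genotypes, so
this rule is a boundary contract, not a common path.)

At each informative site that the evaluated method phased, the orientation
records whether the inferred allele pair matches the gold standard or its
swap. The **SEC** counts orientation changes between consecutive compared
sites; the **SER** divides by the number of informative markers (the
per-pair rate is also reported). A single mis-phased marker flips the
orientation twice and costs SEC = 2 — a worked example kept as a regression
test. Sites the method left unphased are skipped without breaking the chain;
their penalty flows through the yield and the QA adjustment instead.

**Blocks** are maximal runs of constant orientation. A block's raw length is
the bp span of its informative sites; its **QA length** multiplies that by
the fraction of the block's informative sites that are phased. The Fig-style
definition of the adjustment is ambiguous between a block-local and a
global-yield multiplier; both are implemented (`build_blocks(global_yield=)`)
and block-local is the default, since it localizes the penalty to the blocks
that actually lost sites. Unphased sites falling inside the gap around a
switch stay with the upstream block — the gap is not attributable to either
side, and a fixed convention keeps block accounting exactly conservative
(block site counts always sum to the informative count).

**QAN50** is the largest QA length L such that half of all informative SNPs
lie in blocks with QA length at least L; the implementation sorts blocks by
QA length and reads the crossing block, and is tested against an exhaustive
threshold-scan oracle. Genome fractions in blocks above 1/5/10/50 Mb use the
informative span (first to last informative site per chromosome) as the
denominator; chromosome length would mix phasing quality with marker
coverage.

**Pairwise accuracy** at distance d is the probability that two compared
sites separated by about d (a ±10% window) have equal orientation, i.e. an
even number of switch errors between them. Exhaustive pairing is quadratic,
so pairs are subsampled (seeded, default 1e5 per distance); an exact mode
exists for testing. Under a homogeneous Poisson switch process with rate
lambda the quantity has the closed form (1 + exp(-2 lambda d)) / 2, which
the acceptance suite reproduces by simulation.

## Variant and region QC

The genetic-rule filters keep variants that behave like true Mendelian
SNPs: Hardy-Weinberg p > 0.05, offspring-segregation p > 0.05 (offspring
pooled by mating type: het x het 1:2:1, het x hom 1:1; trios only, since a
duo's mating type is unknown), at most one Mendelian inconsistency in the
whole pedigree, chance probability of zero inconsistencies below 1e-12,
MAF at least 0.01, missingness at most 5%. Statistics are computed on the
input snapshot, so the surviving panel does not depend on the order in which
order-independent rules are applied. Masking of opposite homozygotes is a
*final edit* after filtering, followed by a missingness and monomorphism
re-check.

Two design points deserve notes. First, the chance-probability rule: a
variant with no observed inconsistency is only evidence of Mendelian
behaviour if inconsistencies *would* have appeared were the variant an
artifact. The model used is P = (1 - 2 (1-p)^2 p^2)^n_pairs — the
probability of zero opposite-homozygote pairs if genotypes were independent
Hardy-Weinberg draws — with the keep rule P < 1e-12. The formula string is
recorded in every QC report. The rule is intentionally severe: with 279
parent-offspring pairs it only passes variants with MAF above roughly 0.3,
and in small pedigrees it passes nothing (the threshold is first reachable
at 207 pairs for p = 0.5). Users with small pedigrees should raise
`chance_prob` towards 1 deliberately rather than silently.

Second, the HWE test defaults to all genotyped individuals; a
`hwe_founders_only` mode restricts it to individuals without genotyped
parents. Pedigree structure makes individuals non-independent, which
inflates the chi-square slightly in the default mode; the founders-only mode
is the one whose null rejection rate is nominal, and it is what the
package's own calibration checks use. Both modes flag expected counts below
5, where the chi-square approximation is unreliable; the flag never blocks
filtering but calibration claims are only made on unflagged variants.

Region QC combines three masks: the first and last 10 kb of every
chromosome; windows whose depth exceeds 6x the individual's mean (depth
arrives as precomputed per-window summaries — computing it from alignments
is out of scope); and putative map errors. The map-error detector finds
small regions (default at most 1 Mb) bounded by adjacent-marker intervals
with recombination rate above 0.05, then correlates each candidate's
per-meiosis majority origin with the flanking 50 informative markers per
side across meioses: a squared correlation below 0.90 means the region
segregates independently of its neighbourhood — a placement artifact,
whereas a genuine hotspot stays correlated with its flanks. Rates are
recomputed after each masking pass until nothing new is flagged. Crossover
mass is spread fractionally (1/m over the m spanned intervals), which is
unbiased under uniform localization uncertainty. Candidates with fewer
than 20 informative meioses are skipped with a warning rather than judged
on noise. The flank size, span bound and minimum meiosis count are
engineering defaults, stated here because no external reference fixes
them.

## The crossover diagnostic

`detect_crossovers()` assigns, per meiosis and site, which parental
haplotype was transmitted (child homozygous, or child heterozygous with the
other parent homozygous), and calls a crossover at each surviving origin
change after masking runs shorter than `min_support` sites (default 3).
The masking default is the package's replacement for the cited tools'
internal noise heuristics: it suppresses isolated genotyping errors —
which otherwise each fake two crossovers — while keeping double-crossover
sensitivity at sequence density; it is configurable. On clean dense
simulations recovery is calibrated (mean counts match the map length in
Morgans, male/female scaling included) and a genotyping error rate of 1e-3
inflates counts by under 5%.

## The simulator: what it emulates and what it does not

Defaults mirror the kind of study the methodology targets: 264 genotyped
individuals — 83 founders, 98 trio offspring, 83 duo offspring, hence 279
genotyped parent-offspring pairs; Poisson crossovers (no interference) over
a linear genetic map with male/female rates scaled 26/24.5 and 23/24.5
around the map expectation; symmetric genotyping error (default 1e-3,
replacement by a uniform draw among the two other codes) and 1%
missingness; founder allele frequencies uniform on [0.05, 0.95]. The genome
is a scaled-down stand-in — 3 chromosomes of 100 cM / 100 Mb, 1000-8000
markers each depending on the check — because every property tested is
per-chromosome and scale-free; test problem sizes are chosen so the whole
suite runs in about a minute.

Founder haplotypes are independent-site Bernoulli draws by default; an
`ld_copy_prob` knob adds a crude neighbour-copying LD, but it is not
calibrated to any real population's LD decay, and the default leaves it
off so that the documented marginal-frequency guarantees hold exactly.
Consequently the simulator supports the evaluation machinery — not the
phasers themselves: real long-range LD, relatedness structure and variant
density are richer than anything generated here, so passing tests certify
the *metrics and QC logic*, not any particular phaser's field accuracy.
Population phasers are never run in-repo; `corrupt_haplotypes()` stands in
for their output with controllable long switches (Poisson breakpoints with
cumulative label swap — a second switch restores orientation), independent
point switches, and random unphasing. `inject_artifact_variants()` adds
pedigree-ignoring variants (iid Hardy-Weinberg, or all-carriers-het);
`inject_map_errors()` splices a marker block out of its true location and
into a foreign one, preserving spacing, so that the block keeps segregating
with its old neighbourhood while appearing elsewhere — the signature the
map-error detector is built to catch. Coordinates are 1-based bp for
markers throughout, with BED-convention 0-based half-open intervals for
all region masks.

## Numerical and degenerate-input choices

Chi-square tests are Pearson without continuity correction; monomorphic
variants get p = 1 by convention in the HWE test and always fail the
polymorphism rule. The chance probability is computed via `log1p` to stay
accurate at tiny per-pair conflict probabilities. Chromosomes with fewer
than two compared sites yield SEC = 0 with a degenerate flag; empty
distance bins in the pairwise curve are reported as missing with a
warning. Cohort medians use R's standard midpoint convention. All
randomness — simulation, corruption, pair subsampling — sits behind
explicit integer seeds, and seeded helpers restore the caller's RNG state.

## Known limitations

Site-wise Mendelian phasing leaves het x het x het sites unphased, so the
gold standard's informative-site set is allele-frequency dependent. The
pipeline evaluates corrupted truth rather than real phaser output by
construction. Sex chromosomes, multi-allelic variants and indels are out of
scope. The inheritance-vector r² heuristic replaces (and does not
reimplement) the map-confidence-score machinery of dedicated pedigree
software; it is reported as such in its flag table.

## A worked run

```{r, eval = FALSE}
out <- run_pipeline(list(
  seed = 1,
  sim = list(n_chrom = 3, chrom_bp_lengths = 1e8, chrom_cM_lengths = 100,
             n_variants_per_chrom = 2000),
  corruption = list(long_switch_rate_per_Mb = 0.02,
                    point_switch_rate_per_site = 1e-4,
                    unphase_fraction = 0.02)),
  out_dir = "report")
print(out$eval)
print(out$co_summary)
```

`scripts/acceptance.R` packages the same computations as a reproducible
command-line run writing one JSON of headline quantities.
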