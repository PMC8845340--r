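# Genetic-rule variant filters: Hardy-Weinberg, offspring segregation,
# Mendelian-inconsistency count, chance-probability informativeness, MAF,
# missingness; plus the final edits (opposite-homozygote masking,
# missingness and monomorphism re-check).

#' Pearson Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square of observed genotype counts against
#' Hardy-Weinberg proportions at the estimated allele frequency. Monomorphic
#' input gives p = 1 by convention. Vectorized over variants.
#'
#' @param n0,n1,n2 counts of genotypes 0, 1 and 2.
#' @return data.frame(chi2, p, freq, small_counts) where \code{small_counts}
#'   flags any expected cell below 5 (the chi-square approximation is then
#'   unreliable; the flag does not block filtering).
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  .stop_if(any(c(n0, n1, n2) < 0), "counts must be non-negative")
  .stop_if(any(n == 0), "no genotyped individuals")
  p <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - p)^2; e1 <- 2 * n * p * (1 - p); e2 <- n * p^2
  chi2 <- ifelse(p %in% c(0, 1), 0,
                 (n0 - e0)^2 / pmax(e0, .Machine$double.eps) +
                   (n1 - e1)^2 / pmax(e1, .Machine$double.eps) +
                   (n2 - e2)^2 / pmax(e2, .Machine$double.eps))
  pval <- ifelse(p %in% c(0, 1), 1,
                 stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(chi2 = chi2, p = pval, freq = p,
             small_counts = pmin(e0, e1, e2) < 5 & !(p %in% c(0, 1)))
}

#' Offspring segregation test against Mendelian expectations
#'
#' Pools trio offspring by informative mating type at each variant:
#' het x het expects genotypes 0:1:2 in 1:2:1 (2 df), het x hom-ref expects
#' 1:1 over \{0, 1\} (1 df), het x hom-alt expects 1:1 over \{1, 2\} (1 df).
#' Component Pearson chi-squares and degrees of freedom are summed. Variants
#' with no informative mating give p = 1 and are flagged skipped.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param ped a \code{\link{pedigree}}.
#' @return data.frame(chi2, df, p, n_informative, skipped, small_counts),
#'   one row per variant.
#' @export
offspring_segregation_test <- function(genotypes, ped) {
  gm <- genotypes
  trios <- find_trios(ped, gm$sample_ids)
  n_var <- length(gm$pos)
  if (nrow(trios) == 0) {
    return(data.frame(chi2 = rep(0, n_var), df = 0L, p = 1,
                      n_informative = 0L, skipped = TRUE,
                      small_counts = FALSE))
  }
  C <- gm$calls[, match(trios$offspring, gm$sample_ids), drop = FALSE]
  S <- gm$calls[, match(trios$sire, gm$sample_ids), drop = FALSE]
  D <- gm$calls[, match(trios$dam, gm$sample_ids), drop = FALSE]
  known <- !is.na(C) & !is.na(S) & !is.na(D)
  hh <- known & S == 1L & D == 1L
  h0 <- known & ((S == 1L & D == 0L) | (S == 0L & D == 1L))
  h2 <- known & ((S == 1L & D == 2L) | (S == 2L & D == 1L))
  cnt <- function(mask, g) rowSums(mask & C == g, na.rm = TRUE)
  # het x het: 1:2:1
  a0 <- cnt(hh, 0L); a1 <- cnt(hh, 1L); a2 <- cnt(hh, 2L)
  nA <- a0 + a1 + a2
  chiA <- ifelse(nA > 0,
                 (a0 - nA / 4)^2 / pmax(nA / 4, 1e-300) +
                   (a1 - nA / 2)^2 / pmax(nA / 2, 1e-300) +
                   (a2 - nA / 4)^2 / pmax(nA / 4, 1e-300), 0)
  # het x hom-ref: 1:1 over {0, 1}; a genotype-2 offspring here is a
  # Mendelian error, handled by the inconsistency filter, not this test
  b0 <- cnt(h0, 0L); b1 <- cnt(h0, 1L)
  nB <- b0 + b1
  chiB <- ifelse(nB > 0, (b0 - nB / 2)^2 / pmax(nB / 2, 1e-300) * 2, 0)
  # het x hom-alt: 1:1 over {1, 2}
  c1 <- cnt(h2, 1L); c2 <- cnt(h2, 2L)
  nC <- c1 + c2
  chiC <- ifelse(nC > 0, (c1 - nC / 2)^2 / pmax(nC / 2, 1e-300) * 2, 0)

  chi2 <- chiA + chiB + chiC
  df <- 2L * (nA > 0) + (nB > 0) + (nC > 0)
  skipped <- df == 0L
  p <- ifelse(skipped, 1, stats::pchisq(chi2, df = pmax(df, 1L),
                                        lower.tail = FALSE))
  small <- (nA > 0 & nA / 4 < 5) | (nB > 0 & nB / 2 < 5) |
    (nC > 0 & nC / 2 < 5)
  data.frame(chi2 = chi2, df = as.integer(df), p = p,
             n_informative = as.integer(nA + nB + nC), skipped = skipped,
             small_counts = small)
}

#' Chance probability of observing no Mendelian inconsistency
#'
#' Probability that a variant shows zero opposite-homozygote
#' parent-offspring pairs by chance if genotypes were independent
#' Hardy-Weinberg draws: P = (1 - 2 p^2 (1-p)^2 ... ) more precisely
#' (1 - 2 * P0 * P2)^n_pairs with P0 = (1-p)^2, P2 = p^2. A variant is
#' informative for the inconsistency filter only when this probability is
#' very small (default threshold 1e-12): absence of conflicts is then
#' evidence of Mendelian behaviour rather than of low information.
#'
#' @param allele_freq alternate-allele frequency (vectorized).
#' @param n_pairs number of genotyped parent-offspring pairs.
#' @return Probability (same length as \code{allele_freq}).
#' @export
no_inconsistency_probability <- function(allele_freq, n_pairs) {
  .stop_if(any(allele_freq < 0 | allele_freq > 1), "freq must be in [0, 1]")
  .stop_if(any(n_pairs < 0), "n_pairs must be >= 0")
  q <- 2 * (1 - allele_freq)^2 * allele_freq^2
  exp(n_pairs * log1p(-q))
}

#' Apply the genetic-rule variant filters
#'
#' Per-variant statistics are computed on the input snapshot, then the keep
#' rules are applied: HWE p > \code{hwe_p}; segregation p > \code{seg_p};
#' total Mendelian inconsistencies (pairs + impossible trios) <=
#' \code{max_inconsistencies}; chance probability of zero inconsistencies <
#' \code{chance_prob}; MAF >= \code{maf}; missing rate <=
#' \code{max_missing}; polymorphic. As final edits on the surviving panel,
#' opposite-homozygote genotypes are masked to missing and the missingness
#' and monomorphism rules are re-checked.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param ped a \code{\link{pedigree}}.
#' @param thresholds named list overriding any of the defaults
#'   \code{list(hwe_p = 0.05, seg_p = 0.05, max_inconsistencies = 1,
#'   chance_prob = 1e-12, maf = 0.01, max_missing = 0.05)}.
#' @param hwe_founders_only compute the HWE test on founders (samples with
#'   no genotyped parent) only; default FALSE uses all genotyped samples.
#' @return list(genotypes = filtered + masked \code{\link{genotype_matrix}},
#'   report = per-variant data.frame of statistics and pass flags,
#'   attrition = named counts of variants failing each rule,
#'   chance_model = formula string recorded for transparency). Class
#'   \code{"variant_qc"}.
#' @export
apply_variant_filters <- function(genotypes, ped, thresholds = list(),
                                  hwe_founders_only = FALSE) {
  th <- utils::modifyList(list(hwe_p = 0.05, seg_p = 0.05,
                               max_inconsistencies = 1,
                               chance_prob = 1e-12, maf = 0.01,
                               max_missing = 0.05), thresholds)
  gm <- genotypes
  n_var <- length(gm$pos)
  freq <- allele_frequency(gm)
  maf <- pmin(freq, 1 - freq)
  miss <- rowMeans(is.na(gm$calls))

  hwe_samples <- if (hwe_founders_only) {
    po <- parent_offspring_pairs(ped, gm$sample_ids)
    setdiff(gm$sample_ids, unique(po$offspring))
  } else gm$sample_ids
  hsub <- gm$calls[, match(hwe_samples, gm$sample_ids), drop = FALSE]
  hwe <- hwe_test(rowSums(hsub == 0L, na.rm = TRUE),
                  rowSums(hsub == 1L, na.rm = TRUE),
                  rowSums(hsub == 2L, na.rm = TRUE))
  seg <- offspring_segregation_test(gm, ped)
  inc <- find_mendelian_inconsistencies(gm, ped)
  n_inc <- tabulate(inc$variant, nbins = n_var)
  n_pairs <- nrow(parent_offspring_pairs(ped, gm$sample_ids))
  p_chance <- no_inconsistency_probability(ifelse(is.na(freq), 0, freq),
                                           n_pairs)

  pass <- data.frame(
    hwe = hwe$p > th$hwe_p,
    segregation = seg$p > th$seg_p,
    inconsistency = n_inc <= th$max_inconsistencies,
    chance_prob = p_chance < th$chance_prob,
    maf = !is.na(maf) & maf >= th$maf,
    missing = miss <= th$max_missing,
    polymorphic = !is.na(maf) & maf > 0)
  keep <- Reduce(`&`, pass)

  report <- data.frame(chrom = gm$chrom, pos = gm$pos, freq = freq,
                       maf = maf, missing_rate = miss,
                       hwe_chi2 = hwe$chi2, hwe_p = hwe$p,
                       hwe_small_counts = hwe$small_counts,
                       seg_chi2 = seg$chi2, seg_df = seg$df,
                       seg_p = seg$p, seg_skipped = seg$skipped,
                       seg_small_counts = seg$small_counts,
                       n_inconsistencies = n_inc,
                       chance_no_inconsistency = p_chance)
  report <- cbind(report,
                  stats::setNames(pass, paste0("pass_", names(pass))),
                  keep = keep)

  filtered <- subset_variants(gm, keep)
  # final edits on the kept panel
  inc2 <- find_mendelian_inconsistencies(filtered, ped)
  masked <- mask_incompatible_genotypes(filtered, inc2)
  miss2 <- rowMeans(is.na(masked$calls))
  frq2 <- allele_frequency(masked)
  keep2 <- miss2 <= th$max_missing & !is.na(frq2) & frq2 > 0 & frq2 < 1
  final <- subset_variants(masked, keep2)

  attrition <- c(input = n_var,
                 vapply(pass, function(x) sum(!x), 0L),
                 after_filters = sum(keep),
                 masked_genotypes = nrow(inc2),
                 final_edit_removed = sum(!keep2),
                 final = sum(keep2))
  structure(list(genotypes = final, report = report,
                 attrition = attrition, thresholds = th,
                 chance_model =
                   "(1 - 2*(1-p)^2*p^2)^n_pairs, HWE, independent pairs"),
            class = "variant_qc")
}

#' @export
print.variant_qc <- function(x, ...) {
  cat("variant_qc:", x$attrition[["input"]], "variants in,",
      x$attrition[["final"]], "kept\n")
  cat("  failing each rule (on the input snapshot):\n")
  rules <- setdiff(names(x$attrition),
                   c("input", "after_filters", "masked_genotypes",
                     "final_edit_removed", "final"))
  for (r in rules) cat(sprintf("    %-14s %d\n", r, x$attrition[[r]]))
  cat("  genotypes masked in final edits:",
      x$attrition[["masked_genotypes"]], "\n")
  invisible(x)
}
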