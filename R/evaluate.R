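#' Evaluate inferred haplotypes against a gold standard
#'
#' The full metric suite for any set of individuals present in both the
#' truth (gold standard) and the inferred haplotypes: per-individual
#' genome-wide switch error count (SEC), switch error rate (SER), phasing
#' yield, QA block statistics and QAN50; cohort summaries
#' (min/mean/median/max across individuals); genome-fraction table and the
#' pairwise phasing-accuracy curve.
#'
#' @param truth gold-standard \code{\link{haplotype_set}} (or path to a
#'   phased VCF).
#' @param inferred evaluated \code{\link{haplotype_set}} (or path to a
#'   phased VCF).
#' @param individuals samples to evaluate; default: all in common whose
#'   truth contains at least one phased heterozygous site.
#' @param global_yield QA multiplier choice, see \code{\link{build_blocks}}.
#' @param fraction_thresholds_bp see
#'   \code{\link{genome_fraction_in_blocks}}.
#' @param distances_bp,tolerance,max_pairs,seed,exact see
#'   \code{\link{pairwise_accuracy}}.
#' @return An object of class \code{"phasing_eval"}: list(per_individual,
#'   cohort, blocks, genome_fraction, pairwise, profiles, discordance).
#' @export
evaluate_phasing <- function(truth, inferred, individuals = NULL,
                             global_yield = FALSE,
                             fraction_thresholds_bp = c(1, 5, 10, 50) * 1e6,
                             distances_bp = c(0.01, 0.1, 1, 2, 5, 10,
                                              50) * 1e6,
                             tolerance = 0.1, max_pairs = 1e5, seed = 1L,
                             exact = FALSE) {
  if (is.character(truth)) truth <- read_haplotypes(truth)
  if (is.character(inferred)) inferred <- read_haplotypes(inferred)
  .stop_if(length(truth$pos) != length(inferred$pos) ||
             !all(truth$pos == inferred$pos &
                    truth$chrom == inferred$chrom),
           "truth and inferred must share the variant axis")
  common <- intersect(truth$sample_ids, inferred$sample_ids)
  .stop_if(length(common) == 0, "no overlapping individuals")
  if (is.null(individuals)) {
    ti <- match(common, truth$sample_ids)
    has_info <- vapply(ti, function(k)
      any(truth$phased[, k] & truth$hapA[, k] + truth$hapB[, k] == 1L,
          na.rm = TRUE), TRUE)
    individuals <- common[has_info]
  } else {
    missing <- setdiff(individuals, common)
    .stop_if(length(missing) > 0, "individual(s) not in both sets: ",
             paste(missing, collapse = ", "))
  }
  .stop_if(length(individuals) == 0, "no individuals to evaluate")
  chroms <- unique(truth$chrom)

  profiles <- list()
  blocks <- list()
  rows <- list()
  disc <- data.frame(individual = individuals, n_discordant = 0L,
                     n_missing = 0L, stringsAsFactors = FALSE)
  for (ind in individuals) {
    sec <- 0L; n_info <- 0L; n_cmp <- 0L
    b_ind <- list()
    for (ch in chroms) {
      info <- informative_sites(truth, inferred, ind, ch)
      disc[disc$individual == ind, "n_discordant"] <-
        disc[disc$individual == ind, "n_discordant"] + info$n_discordant
      disc[disc$individual == ind, "n_missing"] <-
        disc[disc$individual == ind, "n_missing"] + info$n_missing
      if (length(info$index) == 0) next
      pr <- count_switch_errors(truth, inferred, ind, ch, info = info)
      profiles[[paste(ind, ch, sep = "|")]] <- pr
      sec <- sec + pr$sec
      n_info <- n_info + pr$n_informative
      n_cmp <- n_cmp + pr$n_compared
      b_ind[[ch]] <- build_blocks(pr, global_yield = global_yield)
    }
    b_ind <- do.call(rbind, b_ind)
    blocks[[ind]] <- b_ind
    qan <- if (!is.null(b_ind) && sum(b_ind$n_info) > 0)
      qan_curve(b_ind) else list(qan50 = NA_real_, qan50_snp = NA_real_)
    rows[[ind]] <- data.frame(
      individual = ind, sec = sec,
      ser = if (n_info > 0) sec / n_info else NA_real_,
      yield = if (n_info > 0) n_cmp / n_info else NA_real_,
      n_informative = n_info,
      qan50 = qan$qan50, qan50_snp = qan$qan50_snp,
      block_mean = if (!is.null(b_ind)) mean(b_ind$qa_len) else NA_real_,
      block_median = if (!is.null(b_ind)) stats::median(b_ind$qa_len)
        else NA_real_,
      block_max = if (!is.null(b_ind)) max(b_ind$qa_len) else NA_real_,
      n_blocks = if (!is.null(b_ind)) nrow(b_ind) else 0L,
      stringsAsFactors = FALSE)
  }
  per_ind <- do.call(rbind, rows)
  rownames(per_ind) <- NULL

  summarize <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(min = NA, mean = NA, median = NA,
                                 max = NA))
    c(min = min(x), mean = mean(x), median = stats::median(x), max = max(x))
  }
  metrics <- c("sec", "ser", "yield", "qan50", "qan50_snp", "block_mean",
               "block_median", "block_max")
  cohort <- do.call(rbind, lapply(metrics, function(m)
    data.frame(metric = m, t(summarize(per_ind[[m]])),
               stringsAsFactors = FALSE)))

  all_blocks <- do.call(rbind, blocks)
  rownames(all_blocks) <- NULL
  gf <- if (!is.null(all_blocks) && nrow(all_blocks) > 0)
    genome_fraction_in_blocks(all_blocks, fraction_thresholds_bp) else NULL
  pw <- pairwise_accuracy(profiles, distances_bp = distances_bp,
                          tolerance = tolerance, max_pairs = max_pairs,
                          seed = seed, exact = exact)
  structure(list(per_individual = per_ind, cohort = cohort,
                 blocks = all_blocks, genome_fraction = gf, pairwise = pw,
                 profiles = profiles, discordance = disc),
            class = "phasing_eval")
}

#' @export
print.phasing_eval <- function(x, ...) {
  cat("phasing_eval:", nrow(x$per_individual), "individual(s)\n")
  cat("  cohort summaries (across individuals):\n")
  co <- x$cohort
  for (i in seq_len(nrow(co))) {
    cat(sprintf("    %-12s min %.4g  mean %.4g  median %.4g  max %.4g\n",
                co$metric[i], co$min[i], co$mean[i], co$median[i],
                co$max[i]))
  }
  invisible(x)
}

#' @export
summary.phasing_eval <- function(object, ...) {
  cat("Per-individual metrics:\n")
  print(object$per_individual, row.names = FALSE)
  if (!is.null(object$genome_fraction)) {
    cat("\nFraction of informative span in QA blocks >= threshold:\n")
    print(object$genome_fraction, row.names = FALSE)
  }
  cat("\nPairwise phasing accuracy by distance:\n")
  print(object$pairwise, row.names = FALSE)
  invisible(object)
}
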