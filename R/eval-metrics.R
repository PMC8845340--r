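# Phasing-quality metrics against a trio-derived gold standard: informative
# sites, yield, switch errors, QA blocks, QAN curve, genome fractions,
# pairwise phasing accuracy.

#' Informative sites for one individual and chromosome
#'
#' Sites heterozygous AND phase-known in the truth haplotypes whose
#' genotype agrees between truth and inferred. Genotype-discordant and
#' genotype-missing inferred sites are excluded and counted separately
#' (orientation is undefined there).
#'
#' @param truth,inferred \code{\link{haplotype_set}}s on the same variant
#'   axis.
#' @param individual sample identifier (must be in both sets).
#' @param chrom chromosome identifier.
#' @return list(index (into the chromosome's variants), positions,
#'   n_truth_het_phased, n_discordant, n_missing).
#' @export
informative_sites <- function(truth, inferred, individual, chrom) {
  ti <- match(individual, truth$sample_ids)
  ii <- match(individual, inferred$sample_ids)
  .stop_if(is.na(ti) || is.na(ii),
           "individual '", individual, "' absent from truth or inferred")
  idx <- which(truth$chrom == chrom)
  .stop_if(length(idx) == 0, "no variants on chromosome '", chrom, "'")
  tg <- truth$hapA[idx, ti] + truth$hapB[idx, ti]
  ig <- inferred$hapA[idx, ii] + inferred$hapB[idx, ii]
  het_phased <- !is.na(tg) & tg == 1L & truth$phased[idx, ti]
  concord <- het_phased & !is.na(ig) & ig == tg
  miss <- het_phased & is.na(ig)
  list(index = which(concord), positions = truth$pos[idx][concord],
       n_truth_het_phased = sum(het_phased),
       n_discordant = sum(het_phased & !is.na(ig) & ig != tg),
       n_missing = sum(miss))
}

#' Phasing yield
#'
#' Fraction of informative sites that are phase-known in the inferred
#' haplotypes.
#'
#' @param n_informative number of informative sites.
#' @param n_phased number of those with inferred phase.
#' @return Proportion in [0, 1]; \code{NA} when there are no informative
#'   sites.
#' @export
phasing_yield <- function(n_informative, n_phased) {
  if (n_informative == 0) return(NA_real_)
  n_phased / n_informative
}

#' Count switch errors for one individual-chromosome
#'
#' At each informative site where the inferred haplotypes are phase-known,
#' the orientation records whether the inferred allele pair matches the true
#' haplotypes or their swap. The switch error count (SEC) is the number of
#' orientation changes between consecutive such sites (inferred-unphased
#' sites are skipped without breaking the chain); the switch error rate
#' (SER) divides the SEC by the number of informative markers.
#'
#' @param truth,inferred \code{\link{haplotype_set}}s on the same variant
#'   axis.
#' @param individual,chrom as in \code{\link{informative_sites}}.
#' @param info optional precomputed \code{\link{informative_sites}} result.
#' @return An object of class \code{"switch_profile"}: list(individual,
#'   chrom, positions (all informative sites), compared (logical: inferred
#'   phase-known), orientation (at compared sites: TRUE = same as truth),
#'   switch_after (bp of the compared site preceding each switch), sec, ser,
#'   ser_pairs, yield, n_informative, n_compared, degenerate).
#' @export
count_switch_errors <- function(truth, inferred, individual, chrom,
                                info = NULL) {
  if (is.null(info)) {
    info <- informative_sites(truth, inferred, individual, chrom)
  }
  ti <- match(individual, truth$sample_ids)
  ii <- match(individual, inferred$sample_ids)
  idx <- which(truth$chrom == chrom)
  sel <- idx[info$index]
  phased_inf <- inferred$phased[sel, ii]
  # at an informative compared site both alleles are {0,1}: same orientation
  # iff inferred hapA equals truth hapA
  same <- inferred$hapA[sel, ii] == truth$hapA[sel, ti]
  orient <- same[phased_inf]
  stopifnot(!anyNA(orient))
  sec <- if (length(orient) >= 2) sum(diff(orient) != 0L) else 0L
  n_info <- length(sel)
  pos_cmp <- truth$pos[sel][phased_inf]
  sw <- if (sec > 0) pos_cmp[which(diff(orient) != 0L)] else numeric(0)
  structure(list(individual = individual, chrom = chrom,
                 positions = truth$pos[sel], compared = phased_inf,
                 orientation = orient, switch_after = sw,
                 sec = as.integer(sec),
                 ser = if (n_info > 0) sec / n_info else NA_real_,
                 ser_pairs = if (length(orient) >= 2)
                   sec / (length(orient) - 1) else NA_real_,
                 yield = phasing_yield(n_info, sum(phased_inf)),
                 n_informative = n_info,
                 n_compared = length(orient),
                 degenerate = length(orient) < 2),
            class = "switch_profile")
}

#' Build correctly phased (QA) blocks from a switch profile
#'
#' Blocks are maximal runs of constant orientation over the informative
#' sites, bounded by switch errors and by the chromosome's first and last
#' informative site. A block's raw length is the bp distance from its first
#' to its last informative site (0 for singletons); its quality-adjusted
#' (QA) length multiplies the raw length by the fraction of the block's
#' informative sites that are phased in the inferred haplotypes. A new
#' block starts at the compared site downstream of each switch; unphased
#' informative sites inside a switch gap stay with the upstream block.
#'
#' @param profile a \code{"switch_profile"}.
#' @param global_yield use the chromosome-wide yield as the QA multiplier
#'   for every block instead of the block-local phased fraction.
#' @return data.frame(individual, chrom, first_bp, last_bp, n_info,
#'   n_phased, raw_len, qa_len), one row per block.
#' @export
build_blocks <- function(profile, global_yield = FALSE) {
  p <- profile
  n <- length(p$positions)
  if (n == 0) {
    return(data.frame(individual = character(), chrom = character(),
                      first_bp = numeric(), last_bp = numeric(),
                      n_info = integer(), n_phased = integer(),
                      raw_len = numeric(), qa_len = numeric(),
                      stringsAsFactors = FALSE))
  }
  block_id <- integer(n)
  if (length(p$orientation) >= 2) {
    cmp_idx <- which(p$compared)
    switches_at <- cmp_idx[-1][diff(p$orientation) != 0L]
    # informative sites at/after a switch's downstream compared site open a
    # new block
    block_id <- findInterval(seq_len(n), switches_at)
  }
  out <- lapply(split(seq_len(n), block_id), function(i) {
    data.frame(individual = p$individual, chrom = p$chrom,
               first_bp = p$positions[i[1]],
               last_bp = p$positions[i[length(i)]],
               n_info = length(i), n_phased = sum(p$compared[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$raw_len <- out$last_bp - out$first_bp
  mult <- if (global_yield) p$yield else out$n_phased / out$n_info
  out$qa_len <- out$raw_len * mult
  out
}

#' QAN curve and QAN50 over a set of blocks
#'
#' QANx is the largest QA block length L such that x% of all informative
#' SNPs lie in blocks of QA length >= L: blocks are ranked by decreasing QA
#' length and QANx is the QA length of the block at which the cumulative
#' informative-SNP fraction first reaches x%. The SNP-count analogue ranks
#' blocks by their informative-SNP count instead.
#'
#' @param blocks data.frame as from \code{\link{build_blocks}} (typically
#'   all chromosomes of one individual).
#' @param x_grid percentages to evaluate (always includes 50).
#' @return list(curve = data.frame(x, qan_bp, qan_snp), qan50 = QAN50 in
#'   bp, qan50_snp = SNP-count analogue, total_info).
#' @export
qan_curve <- function(blocks, x_grid = seq(10, 90, by = 10)) {
  x_grid <- sort(unique(c(x_grid, 50)))
  total <- sum(blocks$n_info)
  .stop_if(total == 0, "no informative SNPs in blocks")
  at_frac <- function(value) {
    o <- order(value, decreasing = TRUE)
    cum <- cumsum(blocks$n_info[o]) / total
    vapply(x_grid / 100, function(x) value[o][which(cum >= x)[1]], 0)
  }
  qan_bp <- at_frac(blocks$qa_len)
  qan_snp <- at_frac(as.numeric(blocks$n_info))
  list(curve = data.frame(x = x_grid, qan_bp = qan_bp, qan_snp = qan_snp),
       qan50 = qan_bp[x_grid == 50], qan50_snp = qan_snp[x_grid == 50],
       total_info = total)
}

#' Fraction of the informative genome covered by long QA blocks
#'
#' For each length threshold L, the summed raw bp length of blocks with QA
#' length >= L divided by the total informative span (per chromosome, first
#' to last informative site, summed).
#'
#' @param blocks data.frame as from \code{\link{build_blocks}}.
#' @param thresholds_bp QA length thresholds (default 1, 5, 10, 50 Mb).
#' @return data.frame(threshold_bp, fraction).
#' @export
genome_fraction_in_blocks <- function(blocks,
                                      thresholds_bp = c(1, 5, 10, 50) * 1e6) {
  .stop_if(any(thresholds_bp <= 0), "thresholds must be positive")
  span <- sum(vapply(split(blocks, paste(blocks$individual, blocks$chrom)),
                     function(b) max(b$last_bp) - min(b$first_bp), 0))
  frac <- vapply(thresholds_bp, function(L) {
    if (span == 0) return(0)
    sum(blocks$raw_len[blocks$qa_len >= L]) / span
  }, 0)
  data.frame(threshold_bp = thresholds_bp, fraction = frac)
}

#' Pairwise SNP phasing accuracy by distance
#'
#' For each target distance, pairs of compared informative sites whose
#' separation lies within a relative tolerance window are drawn (up to
#' \code{max_pairs} per distance, seeded; or exhaustively) and a pair is
#' correct iff its two sites have equal orientation, i.e. an even number of
#' switch errors lies between them.
#'
#' @param profiles list of \code{"switch_profile"} objects.
#' @param distances_bp target distances (default 0.01, 0.1, 1, 2, 5, 10,
#'   50 Mb).
#' @param tolerance relative half-width of the distance window (default
#'   0.1).
#' @param max_pairs sampling cap per distance bin.
#' @param seed integer seed for the sampling.
#' @param exact enumerate all pairs instead of sampling.
#' @return data.frame(distance_bp, prob, n_pairs); prob is \code{NA} with a
#'   warning for bins with no pairs.
#' @export
pairwise_accuracy <- function(profiles,
                              distances_bp = c(0.01, 0.1, 1, 2, 5, 10,
                                               50) * 1e6,
                              tolerance = 0.1, max_pairs = 1e5,
                              seed = 1L, exact = FALSE) {
  .stop_if(any(distances_bp <= 0), "distances must be positive")
  if (inherits(profiles, "switch_profile")) profiles <- list(profiles)
  pp <- lapply(profiles, function(p) {
    list(pos = p$positions[p$compared], o = p$orientation)
  })
  pp <- Filter(function(x) length(x$pos) >= 2, pp)
  out <- data.frame(distance_bp = distances_bp, prob = NA_real_,
                    n_pairs = 0L)
  if (length(pp) == 0) {
    warning("no profiles with >= 2 compared sites")
    return(out)
  }
  .with_seed(seed, {
    for (d in seq_along(distances_bp)) {
      lo <- distances_bp[d] * (1 - tolerance)
      hi <- distances_bp[d] * (1 + tolerance)
      n_ok <- 0; n_tot <- 0
      if (exact) {
        for (x in pp) {
          j_lo <- findInterval(x$pos + lo - 1e-9, x$pos) + 1L
          j_hi <- findInterval(x$pos + hi + 1e-9, x$pos)
          for (i in seq_along(x$pos)) {
            if (j_hi[i] < j_lo[i]) next
            js <- j_lo[i]:j_hi[i]
            n_tot <- n_tot + length(js)
            n_ok <- n_ok + sum(x$o[js] == x$o[i])
          }
        }
      } else {
        # sample first sites proportionally to profile size, then a uniform
        # partner within the window
        sizes <- vapply(pp, function(x) length(x$pos), 0)
        probs <- sizes / sum(sizes)
        drawn <- 0; attempts <- 0
        while (drawn < max_pairs && attempts < 20) {
          attempts <- attempts + 1
          batch <- min(max_pairs - drawn + 1000, max_pairs)
          which_p <- sample.int(length(pp), batch, replace = TRUE,
                                prob = probs)
          for (pi in unique(which_p)) {
            x <- pp[[pi]]
            k <- sum(which_p == pi)
            i <- sample.int(length(x$pos), k, replace = TRUE)
            j_lo <- findInterval(x$pos[i] + lo - 1e-9, x$pos) + 1L
            j_hi <- findInterval(x$pos[i] + hi + 1e-9, x$pos)
            ok <- j_hi >= j_lo
            if (!any(ok)) next
            i <- i[ok]; j_lo <- j_lo[ok]; j_hi <- j_hi[ok]
            j <- j_lo + floor(stats::runif(length(i)) *
                                (j_hi - j_lo + 1))
            take <- seq_len(min(length(i), max_pairs - drawn))
            i <- i[take]; j <- j[take]
            n_tot <- n_tot + length(i)
            n_ok <- n_ok + sum(x$o[i] == x$o[j])
            drawn <- drawn + length(i)
          }
          if (drawn == 0 && attempts >= 5) break
        }
      }
      if (n_tot == 0) {
        warning("no pairs at distance ", distances_bp[d])
      } else {
        out$prob[d] <- n_ok / n_tot
        out$n_pairs[d] <- n_tot
      }
    }
  })
  out
}
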