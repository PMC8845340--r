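# Crossover identification in parent-offspring meioses ("proband and
# gamete") and the crossover-count data-quality diagnostic.

#' Assign parental origin along one meiosis
#'
#' For one chromosome of a parent-offspring pair, deduces at each site which
#' allele the focal parent transmitted (child homozygous: that allele; child
#' heterozygous with the other parent homozygous: the remaining allele) and,
#' where the parent is phased-heterozygous, which parental haplotype carries
#' it (1 = hapA, 2 = hapB). All other sites are unknown. Sites where the
#' deduced allele is incompatible with the parent's genotype are counted as
#' conflicts and excluded.
#'
#' @param parent_hapA,parent_hapB,parent_phased parent haplotype alleles and
#'   phase mask for the chromosome.
#' @param child_gt child genotype codes.
#' @param other_parent_gt other parent's genotype codes (NA vector if
#'   ungenotyped).
#' @param positions 1-based bp positions.
#' @return list(positions, origin (integer 1/2), n_conflict, n_informative).
#' @export
assign_parental_origin <- function(parent_hapA, parent_hapB, parent_phased,
                                   child_gt, other_parent_gt, positions) {
  n <- length(positions)
  .stop_if(length(child_gt) != n || length(parent_hapA) != n,
           "input vectors must have equal length")
  transmitted <- rep(NA_integer_, n)
  transmitted[!is.na(child_gt) & child_gt == 0L] <- 0L
  transmitted[!is.na(child_gt) & child_gt == 2L] <- 1L
  het <- !is.na(child_gt) & child_gt == 1L
  transmitted[het & !is.na(other_parent_gt) & other_parent_gt == 0L] <- 1L
  transmitted[het & !is.na(other_parent_gt) & other_parent_gt == 2L] <- 0L

  pg <- parent_hapA + parent_hapB
  conflict <- !is.na(transmitted) & !is.na(pg) &
    ((pg == 0L & transmitted == 1L) | (pg == 2L & transmitted == 0L))
  informative <- !is.na(transmitted) & !conflict & parent_phased &
    !is.na(pg) & pg == 1L
  origin <- ifelse(parent_hapA == transmitted, 1L, 2L)[informative]
  list(positions = positions[informative], origin = as.integer(origin),
       n_conflict = sum(conflict), n_informative = sum(informative))
}

#' Call crossovers from a parental-origin vector
#'
#' Run-length encodes the origin vector, masks runs supported by fewer than
#' \code{min_support} sites as noise (isolated genotyping errors), merges
#' the surviving runs, and emits one crossover per boundary between
#' consecutive runs of different origin. The localization interval runs from
#' the last supporting site before the crossover to the first site after.
#'
#' @param origin integer vector of parental origins (1/2), unknowns already
#'   removed.
#' @param positions bp positions of the origin sites (sorted).
#' @param min_support minimum number of consecutive same-origin sites for a
#'   run to count as real (default 3).
#' @return data.frame(start, end, left_origin, right_origin, left_support,
#'   right_support), one row per crossover.
#' @export
call_crossovers <- function(origin, positions, min_support = 3L) {
  .stop_if(min_support < 1, "min_support must be >= 1")
  empty <- data.frame(start = numeric(), end = numeric(),
                      left_origin = integer(), right_origin = integer(),
                      left_support = integer(), right_support = integer())
  if (length(origin) == 0) return(empty)
  r <- rle(origin)
  keep <- r$lengths >= min_support
  if (!any(keep)) return(empty)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  starts <- starts[keep]; ends <- ends[keep]
  vals <- r$values[keep]; lens <- r$lengths[keep]
  # merge surviving adjacent runs with equal origin
  m_start <- m_end <- integer(0); m_val <- m_len <- integer(0)
  for (i in seq_along(vals)) {
    k <- length(m_val)
    if (k > 0 && m_val[k] == vals[i]) {
      m_end[k] <- ends[i]; m_len[k] <- m_len[k] + lens[i]
    } else {
      m_start <- c(m_start, starts[i]); m_end <- c(m_end, ends[i])
      m_val <- c(m_val, vals[i]); m_len <- c(m_len, lens[i])
    }
  }
  if (length(m_val) < 2) return(empty)
  i <- seq_len(length(m_val) - 1)
  data.frame(start = positions[m_end[i]], end = positions[m_start[i + 1]],
             left_origin = m_val[i], right_origin = m_val[i + 1],
             left_support = m_len[i], right_support = m_len[i + 1])
}

#' Detect crossovers in all meioses of a pedigree
#'
#' Runs \code{\link{assign_parental_origin}} and
#' \code{\link{call_crossovers}} for every genotyped parent-offspring pair
#' and chromosome. Parent haplotypes may come from Mendelian phasing, from
#' simulation truth, or from any phased source.
#'
#' @param parent_haps a \code{\link{haplotype_set}} containing the parents.
#' @param genotypes a \code{\link{genotype_matrix}} with the offspring (and
#'   other parents) on the same variant axis.
#' @param ped a \code{\link{pedigree}}.
#' @param min_support see \code{\link{call_crossovers}}.
#' @return list(calls = data.frame(parent, offspring, chrom, start, end),
#'   meioses = data.frame(parent, offspring, parent_sex, n_conflict),
#'   origins = list of per-meiosis per-chromosome origin vectors, named
#'   "parent|offspring"; each element is a list of
#'   list(chrom, positions, origin)).
#' @export
detect_crossovers <- function(parent_haps, genotypes, ped,
                              min_support = 3L) {
  gm <- genotypes
  po <- parent_offspring_pairs(ped, gm$sample_ids)
  po <- po[po$parent %in% parent_haps$sample_ids, , drop = FALSE]
  .stop_if(nrow(po) == 0, "no meioses with a phased parent")
  .stop_if(length(parent_haps$pos) != length(gm$pos) ||
             !all(parent_haps$pos == gm$pos & parent_haps$chrom == gm$chrom),
           "parent haplotypes and genotypes must share the variant axis")
  chroms <- unique(gm$chrom)
  call_rows <- list(); origins <- list()
  n_confl <- integer(nrow(po))
  for (i in seq_len(nrow(po))) {
    pcol <- match(po$parent[i], parent_haps$sample_ids)
    ccol <- match(po$offspring[i], gm$sample_ids)
    orow <- ped[match(po$offspring[i], ped$id), ]
    other_id <- if (po$parent_role[i] == "sire") orow$dam else orow$sire
    ocol <- if (!is.na(other_id)) match(other_id, gm$sample_ids) else NA
    key <- paste(po$parent[i], po$offspring[i], sep = "|")
    per_chrom <- list()
    for (ch in chroms) {
      idx <- which(gm$chrom == ch)
      hidx <- which(parent_haps$chrom == ch)
      ov <- assign_parental_origin(
        parent_haps$hapA[hidx, pcol], parent_haps$hapB[hidx, pcol],
        parent_haps$phased[hidx, pcol],
        gm$calls[idx, ccol],
        if (!is.na(ocol)) gm$calls[idx, ocol] else rep(NA_integer_,
                                                      length(idx)),
        gm$pos[idx])
      n_confl[i] <- n_confl[i] + ov$n_conflict
      per_chrom[[ch]] <- list(chrom = ch, positions = ov$positions,
                              origin = ov$origin)
      cc <- call_crossovers(ov$origin, ov$positions, min_support)
      if (nrow(cc) > 0) {
        call_rows[[length(call_rows) + 1]] <-
          data.frame(parent = po$parent[i], offspring = po$offspring[i],
                     chrom = ch, start = cc$start, end = cc$end,
                     stringsAsFactors = FALSE)
      }
    }
    origins[[key]] <- per_chrom
  }
  calls <- if (length(call_rows) > 0) do.call(rbind, call_rows) else
    data.frame(parent = character(), offspring = character(),
               chrom = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  meioses <- data.frame(parent = po$parent, offspring = po$offspring,
                        parent_sex = ped$sex[match(po$parent, ped$id)],
                        n_conflict = n_confl, stringsAsFactors = FALSE)
  list(calls = calls, meioses = meioses, origins = origins)
}

#' Summarize crossover counts per meiosis
#'
#' The data-quality diagnostic: genome-wide crossover counts per meiosis,
#' means overall and by parent sex, and the inflation ratio against an
#' expected count (e.g. the genetic map length in Morgans, or counts from a
#' high-quality reference map). Counts far above expectation indicate
#' genotyping or marker-order errors.
#'
#' @param calls crossover calls as from \code{\link{detect_crossovers}}.
#' @param meioses data.frame(parent, offspring, parent_sex) listing all
#'   meioses (so zero-crossover meioses are counted).
#' @param expected_per_meiosis optional expectation for the inflation ratio.
#' @return An object of class \code{"co_summary"}: list(per_meiosis,
#'   mean_overall, mean_by_sex, expected, inflation).
#' @export
co_summary <- function(calls, meioses, expected_per_meiosis = NULL) {
  key <- paste(meioses$parent, meioses$offspring, sep = "|")
  cnt <- integer(length(key))
  if (nrow(calls) > 0) {
    ck <- paste(calls$parent, calls$offspring, sep = "|")
    tab <- table(ck)
    m <- match(key, names(tab))
    cnt[!is.na(m)] <- as.integer(tab[m[!is.na(m)]])
  }
  per <- data.frame(parent = meioses$parent, offspring = meioses$offspring,
                    parent_sex = meioses$parent_sex, n_co = cnt,
                    stringsAsFactors = FALSE)
  by_sex <- tapply(per$n_co, per$parent_sex, mean)
  res <- list(per_meiosis = per,
              mean_overall = mean(per$n_co),
              mean_by_sex = by_sex,
              expected = expected_per_meiosis,
              inflation = if (!is.null(expected_per_meiosis))
                mean(per$n_co) / expected_per_meiosis else NA_real_)
  class(res) <- "co_summary"
  res
}

#' @export
print.co_summary <- function(x, ...) {
  cat("co_summary:", nrow(x$per_meiosis), "meioses\n")
  cat(sprintf("  mean crossovers/meiosis: %.2f\n", x$mean_overall))
  for (s in names(x$mean_by_sex)) {
    cat(sprintf("    %s parents: %.2f\n", s, x$mean_by_sex[[s]]))
  }
  if (!is.null(x$expected)) {
    cat(sprintf("  expected: %.2f  inflation ratio: %.2f\n",
                x$expected, x$inflation))
  }
  invisible(x)
}
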