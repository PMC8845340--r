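# Trio/duo Mendelian phasing: the gold standard for haplotype evaluation.
#
# Site-wise rules only. A parent with genotype g can transmit allele 0
# unless g == 2 and allele 1 unless g == 0 (a missing genotype can transmit
# either). An offspring allele is assigned iff every parental-transmission
# combination compatible with the three genotypes agrees on it.

# vectorized core: returns paternal/maternal assignment (NA = unresolved)
# and an inconsistency flag, for genotype code vectors
.phase_sites <- function(child, sire, dam) {
  s_can0 <- is.na(sire) | sire != 2L
  s_can1 <- is.na(sire) | sire != 0L
  d_can0 <- is.na(dam) | dam != 2L
  d_can1 <- is.na(dam) | dam != 0L
  pat <- rep(NA_integer_, length(child))
  mat <- rep(NA_integer_, length(child))
  incons <- rep(FALSE, length(child))

  hom0 <- !is.na(child) & child == 0L
  hom2 <- !is.na(child) & child == 2L
  het <- !is.na(child) & child == 1L

  ok0 <- s_can0 & d_can0
  pat[hom0 & ok0] <- 0L; mat[hom0 & ok0] <- 0L
  incons[hom0 & !ok0] <- TRUE

  ok2 <- s_can1 & d_can1
  pat[hom2 & ok2] <- 1L; mat[hom2 & ok2] <- 1L
  incons[hom2 & !ok2] <- TRUE

  optA <- s_can0 & d_can1   # paternal 0, maternal 1
  optB <- s_can1 & d_can0   # paternal 1, maternal 0
  a_only <- het & optA & !optB
  b_only <- het & optB & !optA
  pat[a_only] <- 0L; mat[a_only] <- 1L
  pat[b_only] <- 1L; mat[b_only] <- 0L
  incons[het & !optA & !optB] <- TRUE

  list(pat = pat, mat = mat, inconsistent = incons)
}

#' Phase a single trio site by Mendelian segregation rules
#'
#' @param child_gt,sire_gt,dam_gt genotype codes in \{0, 1, 2, NA\}; use
#'   \code{NA} for an ungenotyped parent (duo).
#' @return list(paternal, maternal, inconsistent): alleles are \code{NA}
#'   when unresolved; no allele is assigned at inconsistent sites.
#' @export
phase_trio_site <- function(child_gt, sire_gt, dam_gt) {
  chk <- function(g, what) {
    .stop_if(length(g) != 1 || (!is.na(g) && !(g %in% 0:2)),
             what, " genotype must be a single code in {0, 1, 2, NA}")
    as.integer(g)
  }
  r <- .phase_sites(chk(child_gt, "child"), chk(sire_gt, "sire"),
                    chk(dam_gt, "dam"))
  list(paternal = r$pat, maternal = r$mat, inconsistent = r$inconsistent)
}

#' Build gold-standard haplotypes for a pedigree by Mendelian rules
#'
#' Applies site-wise Mendelian segregation rules to every trio (both parents
#' genotyped) and duo (one parent genotyped) offspring: hapA is the paternal
#' and hapB the maternal allele. Sites that cannot be resolved (e.g. all
#' three heterozygous) and inconsistent sites stay unphased. Individuals
#' that are not trio/duo offspring are carried through unphased.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param ped a \code{\link{pedigree}}.
#' @return list(haplotypes = \code{\link{haplotype_set}},
#'   inconsistencies = data.frame as from
#'   \code{\link{find_mendelian_inconsistencies}} restricted to the phased
#'   families).
#' @export
phase_pedigree <- function(genotypes, ped) {
  gm <- genotypes
  trios <- find_trios(ped, gm$sample_ids)
  duos <- find_duos(ped, gm$sample_ids)
  .stop_if(nrow(trios) + nrow(duos) == 0,
           "no trios or duos among the genotyped samples")
  n_var <- length(gm$pos); n_samp <- length(gm$sample_ids)
  hapA <- matrix(NA_integer_, n_var, n_samp)
  hapB <- matrix(NA_integer_, n_var, n_samp)
  phased <- matrix(FALSE, n_var, n_samp)
  # unphased carriers still encode their genotype as an allele pair
  g_all <- gm$calls
  hapA[] <- ifelse(is.na(g_all), NA_integer_, as.integer(g_all > 1L))
  hapB[] <- ifelse(is.na(g_all), NA_integer_, as.integer(g_all > 0L))

  fams <- rbind(
    if (nrow(trios) > 0)
      data.frame(offspring = trios$offspring, sire = trios$sire,
                 dam = trios$dam, stringsAsFactors = FALSE),
    if (nrow(duos) > 0)
      data.frame(offspring = duos$offspring,
                 sire = ifelse(duos$parent_role == "sire", duos$parent, NA),
                 dam = ifelse(duos$parent_role == "dam", duos$parent, NA),
                 stringsAsFactors = FALSE))
  for (i in seq_len(nrow(fams))) {
    o <- match(fams$offspring[i], gm$sample_ids)
    sg <- if (!is.na(fams$sire[i])) gm$calls[, match(fams$sire[i], gm$sample_ids)]
          else rep(NA_integer_, n_var)
    dg <- if (!is.na(fams$dam[i])) gm$calls[, match(fams$dam[i], gm$sample_ids)]
          else rep(NA_integer_, n_var)
    r <- .phase_sites(gm$calls[, o], sg, dg)
    res <- !is.na(r$pat) & !is.na(r$mat)
    hapA[res, o] <- r$pat[res]
    hapB[res, o] <- r$mat[res]
    phased[res, o] <- TRUE
  }
  hs <- haplotype_set(gm$chrom, gm$pos, gm$sample_ids, hapA, hapB, phased)
  inc <- find_mendelian_inconsistencies(gm, ped)
  list(haplotypes = hs, inconsistencies = inc)
}

#' List Mendelian inconsistencies in parent-offspring pairs and trios
#'
#' Opposite homozygotes (0 vs 2) in any genotyped parent-offspring pair, and
#' trio configurations with no compatible transmission that are not already
#' explained by an opposite-homozygote pair (e.g. a heterozygous child of
#' two hom-ref parents).
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param ped a \code{\link{pedigree}}.
#' @return data.frame(variant, chrom, pos, offspring, parent1, parent2,
#'   kind) with kind in "opposite_homozygote_pair" / "impossible_trio";
#'   pair records carry the conflicting parent in \code{parent1}.
#' @export
find_mendelian_inconsistencies <- function(genotypes, ped) {
  gm <- genotypes
  pairs <- parent_offspring_pairs(ped, gm$sample_ids)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    o <- gm$calls[, match(pairs$offspring[i], gm$sample_ids)]
    p <- gm$calls[, match(pairs$parent[i], gm$sample_ids)]
    v <- which(!is.na(o) & !is.na(p) & abs(o - p) == 2L)
    if (length(v) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, chrom = gm$chrom[v], pos = gm$pos[v],
        offspring = pairs$offspring[i], parent1 = pairs$parent[i],
        parent2 = NA_character_, kind = "opposite_homozygote_pair",
        stringsAsFactors = FALSE)
    }
  }
  trios <- find_trios(ped, gm$sample_ids)
  for (i in seq_len(nrow(trios))) {
    cg <- gm$calls[, match(trios$offspring[i], gm$sample_ids)]
    sg <- gm$calls[, match(trios$sire[i], gm$sample_ids)]
    dg <- gm$calls[, match(trios$dam[i], gm$sample_ids)]
    r <- .phase_sites(cg, sg, dg)
    pair_confl <- (!is.na(cg) & !is.na(sg) & abs(cg - sg) == 2L) |
      (!is.na(cg) & !is.na(dg) & abs(cg - dg) == 2L)
    v <- which(r$inconsistent & !pair_confl)
    if (length(v) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, chrom = gm$chrom[v], pos = gm$pos[v],
        offspring = trios$offspring[i], parent1 = trios$sire[i],
        parent2 = trios$dam[i], kind = "impossible_trio",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(variant = integer(), chrom = character(),
                      pos = integer(), offspring = character(),
                      parent1 = character(), parent2 = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$variant), , drop = FALSE]
}

#' Mask genotypes involved in Mendelian inconsistencies
#'
#' Opposite-homozygote pairs: both members set to missing at the site (the
#' true error source is unknown). Impossible trios: all three members set to
#' missing.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param records output of \code{\link{find_mendelian_inconsistencies}}.
#' @return The masked \code{\link{genotype_matrix}}.
#' @export
mask_incompatible_genotypes <- function(genotypes, records) {
  gm <- genotypes
  for (i in seq_len(nrow(records))) {
    v <- records$variant[i]
    members <- c(records$offspring[i], records$parent1[i],
                 records$parent2[i])
    members <- members[!is.na(members)]
    gm$calls[v, match(members, gm$sample_ids)] <- NA_integer_
  }
  gm
}
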