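# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementation paths.

# --- Mendelian compatibility oracle -----------------------------------------
# Enumerates parental allele pairs explicitly: a genotype code corresponds to
# an unordered allele pair; a parent transmits either of its two alleles; a
# trio is compatible iff some transmission pair sums to the child genotype.
# Unknown (NA) genotypes range over all three codes.
oracle_phase_site <- function(child, sire, dam) {
  gt_pairs <- list(`0` = c(0L, 0L), `1` = c(0L, 1L), `2` = c(1L, 1L))
  expand <- function(g) if (is.na(g)) 0:2 else g
  pats <- c(); mats <- c()
  for (s in expand(sire)) for (d in expand(dam)) for (c_ in expand(child)) {
    if (!is.na(child) && c_ != child) next
    for (a_p in gt_pairs[[as.character(s)]]) {
      for (a_m in gt_pairs[[as.character(d)]]) {
        if (a_p + a_m == c_) { pats <- c(pats, a_p); mats <- c(mats, a_m) }
      }
    }
  }
  if (length(pats) == 0) {
    return(list(paternal = NA_integer_, maternal = NA_integer_,
                inconsistent = TRUE))
  }
  if (is.na(child)) {
    # no constraint from the child: nothing is assignable
    return(list(paternal = NA_integer_, maternal = NA_integer_,
                inconsistent = FALSE))
  }
  list(paternal = if (length(unique(pats)) == 1) pats[1] else NA_integer_,
       maternal = if (length(unique(mats)) == 1) mats[1] else NA_integer_,
       inconsistent = FALSE)
}

# --- switch-error oracle ----------------------------------------------------
# Compares the allele combination at every pair of consecutive compared
# sites between inferred and truth, literally: a discrepancy (pair neither
# equal to the truth's pair nor to its swap at both ends coherently) is one
# switch error.
oracle_sec <- function(truth_hapA, inf_hapA, compared) {
  a_t <- truth_hapA[compared]; a_i <- inf_hapA[compared]
  if (length(a_t) < 2) return(0L)
  sec <- 0L
  for (k in seq_len(length(a_t) - 1)) {
    pair_truth <- c(a_t[k], a_t[k + 1])
    pair_inf <- c(a_i[k], a_i[k + 1])
    same <- all(pair_inf == pair_truth)
    swapped <- all(pair_inf == (1L - pair_truth))
    if (!same && !swapped) sec <- sec + 1L
  }
  sec
}

# --- QAN50 threshold-scan oracle --------------------------------------------
# QAN50 = the largest candidate QA length L such that blocks with QA length
# >= L contain at least half of all informative SNPs.
oracle_qan50 <- function(qa_len, n_info) {
  total <- sum(n_info)
  best <- NA_real_
  for (L in sort(unique(qa_len), decreasing = TRUE)) {
    if (sum(n_info[qa_len >= L]) >= total / 2) return(L)
  }
  best
}

# --- small fixture builders -------------------------------------------------
# fully phased single-sample haplotype set with all-heterozygous sites
make_het_truth <- function(positions, hapA, chrom = "chr1",
                           sample_id = "S1") {
  haplotype_set(rep(chrom, length(positions)), positions, sample_id,
                hapA = matrix(hapA, ncol = 1),
                hapB = matrix(1L - hapA, ncol = 1),
                phased = matrix(TRUE, length(positions), 1))
}

# flip the phase (swap hapA/hapB) of selected site indices of one sample
flip_sites <- function(hs, sample_id, idx) {
  s <- match(sample_id, hs$sample_ids)
  tmp <- hs$hapA[idx, s]
  hs$hapA[idx, s] <- hs$hapB[idx, s]
  hs$hapB[idx, s] <- tmp
  hs
}

small_sim <- function(...) {
  args <- utils::modifyList(
    list(n_chrom = 2, chrom_bp_lengths = 1e7, chrom_cM_lengths = 50,
         n_variants_per_chrom = 200, n_founders = 10, n_trios = 8,
         n_duos = 4, genotype_error_rate = 0, missing_rate = 0, seed = 11),
    list(...))
  simulate_dataset(do.call(sim_config, args))
}
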