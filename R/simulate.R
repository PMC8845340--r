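#' Simulation configuration
#'
#' Parameters of the pedigree genotype simulator. Defaults emulate the kind
#' of data the evaluation pipeline targets: a trio-rich cattle-style pedigree
#' of 264 genotyped individuals (83 founders, 98 trio offspring, 83 duo
#' offspring, i.e. 279 genotyped parent-offspring pairs), Poisson
#' recombination over a genetic map with sex-specific rates scaled so that a
#' 24.5-Morgan genome yields on average 26 crossovers in males and 23 in
#' females, light genotyping error and missingness. The genome itself is a
#' scaled-down stand-in (3 chromosomes by default) whose per-chromosome map
#' lengths are configurable.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_bp_lengths bp length per chromosome (recycled).
#' @param chrom_cM_lengths genetic length per chromosome in cM (recycled).
#' @param n_variants_per_chrom markers per chromosome (recycled).
#' @param allele_freq alternate-allele frequency model for founder
#'   haplotypes: a single number (all sites), a length-2 range for a uniform
#'   draw, or a function \code{f(n)} returning \code{n} frequencies.
#' @param ld_copy_prob probability that a founder haplotype copies its own
#'   allele from the previous site instead of drawing fresh (0 = independent
#'   sites; a pragmatic linkage-disequilibrium stand-in).
#' @param n_founders,n_trios,n_duos pedigree composition: genotyped founders,
#'   offspring with both parents genotyped, offspring with exactly one.
#' @param sex_rate_scale length-2 named vector \code{c(male=, female=)}
#'   multiplying the crossover rate per meiosis.
#' @param genotype_error_rate per-genotype probability of replacement by a
#'   uniform draw among the two other codes.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_chrom = 3,
                       chrom_bp_lengths = 1e8,
                       chrom_cM_lengths = 100,
                       n_variants_per_chrom = 1000,
                       allele_freq = c(0.05, 0.95),
                       ld_copy_prob = 0,
                       n_founders = 83,
                       n_trios = 98,
                       n_duos = 83,
                       sex_rate_scale = c(male = 26 / 24.5,
                                          female = 23 / 24.5),
                       genotype_error_rate = 0.001,
                       missing_rate = 0.01,
                       seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_bp_lengths = rep_len(chrom_bp_lengths, n_chrom),
              chrom_cM_lengths = rep_len(chrom_cM_lengths, n_chrom),
              n_variants_per_chrom = rep_len(as.integer(n_variants_per_chrom),
                                             n_chrom),
              allele_freq = allele_freq,
              ld_copy_prob = ld_copy_prob,
              n_founders = as.integer(n_founders),
              n_trios = as.integer(n_trios),
              n_duos = as.integer(n_duos),
              sex_rate_scale = sex_rate_scale,
              genotype_error_rate = genotype_error_rate,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  .stop_if(cfg$n_chrom < 1 || any(cfg$n_variants_per_chrom < 1),
           "counts must be positive")
  .stop_if(any(cfg$chrom_cM_lengths < 0), "cM lengths must be >= 0")
  probs <- c(cfg$ld_copy_prob, cfg$genotype_error_rate, cfg$missing_rate)
  .stop_if(any(probs < 0 | probs > 1), "probabilities must be in [0, 1]")
  .stop_if(cfg$n_founders < 2 && (cfg$n_trios > 0 || cfg$n_duos > 0),
           "need at least 2 founders (a sire and a dam) to form offspring")
  class(cfg) <- "sim_config"
  cfg
}

.draw_freqs <- function(model, n) {
  if (is.function(model)) return(model(n))
  if (length(model) == 1) return(rep(model, n))
  stats::runif(n, model[1], model[2])
}

# evenly spaced marker grid with a linear cM scale
.sim_map <- function(cfg) {
  parts <- lapply(seq_len(cfg$n_chrom), function(k) {
    n <- cfg$n_variants_per_chrom[k]
    L <- cfg$chrom_bp_lengths[k]
    bp <- unique(round(seq(L / (n + 1), L * n / (n + 1), length.out = n)))
    data.frame(chrom = paste0("chr", k),
               id = paste0("chr", k, "_m", seq_along(bp)),
               cM = bp / L * cfg$chrom_cM_lengths[k],
               bp = as.integer(bp), stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, parts)
  marker_map(m$chrom, m$id, m$cM, m$bp)
}

#' Simulate founder haplotypes
#'
#' Each site's allele is Bernoulli with the site's model frequency,
#' independently across haplotypes; with \code{ld_copy_prob > 0} a haplotype
#' copies its previous-site allele with that probability instead.
#'
#' @param config a \code{\link{sim_config}}; its \code{seed} is used unless
#'   the caller has already seeded the RNG and passes \code{seed = NULL}.
#' @param n_founders number of diploid founders (2x haplotypes simulated).
#' @param map optional \code{\link{marker_map}}; defaults to the config grid.
#' @param freqs optional per-site frequencies (drawn from the model if NULL).
#' @param seed overrides \code{config$seed}; \code{NULL} uses the current RNG
#'   state.
#' @return A fully phased \code{\link{haplotype_set}} with samples
#'   \code{F001...}; haplotype pair (hapA, hapB) per founder.
#' @export
simulate_founder_haplotypes <- function(config, n_founders = config$n_founders,
                                        map = NULL, freqs = NULL,
                                        seed = config$seed) {
  run <- function() {
    m <- map %||% .sim_map(config)
    f <- freqs %||% .draw_freqs(config$allele_freq, nrow(m))
    H <- .sim_founder_matrix(f, 2L * n_founders, m$chrom,
                             config$ld_copy_prob)
    ids <- sprintf("F%03d", seq_len(n_founders))
    haplotype_set(m$chrom, m$bp, ids,
                  hapA = H[, seq(1, 2 * n_founders, by = 2), drop = FALSE],
                  hapB = H[, seq(2, 2 * n_founders, by = 2), drop = FALSE],
                  phased = matrix(TRUE, nrow(m), n_founders))
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

.sim_founder_matrix <- function(freqs, n_hap, chrom, ld_copy_prob) {
  n_site <- length(freqs)
  fresh <- matrix(stats::rbinom(n_site * n_hap, 1L, freqs),
                  nrow = n_site, ncol = n_hap)
  if (ld_copy_prob <= 0) return(fresh)
  H <- fresh
  copy <- matrix(stats::runif(n_site * n_hap) < ld_copy_prob,
                 nrow = n_site, ncol = n_hap)
  new_chrom <- c(TRUE, chrom[-1] != chrom[-n_site])
  for (i in seq_len(n_site)[-1]) {
    if (new_chrom[i]) next
    H[i, ] <- ifelse(copy[i, ], H[i - 1, ], fresh[i, ])
  }
  H
}

#' Simulate one gamete from a phased parent
#'
#' The crossover count is Poisson with mean (chromosome cM length / 100) x
#' \code{sex_scale}; crossover positions are uniform on the cM scale and
#' mapped to bp by linear interpolation on the marker map. The gamete starts
#' on a uniformly chosen parental haplotype and alternates at each crossover.
#' Uses the current RNG state (seed upstream).
#'
#' @param hapA,hapB parent allele vectors for one chromosome (fully phased).
#' @param map_chrom \code{\link{marker_map}} rows for this chromosome.
#' @param sex_scale crossover-rate multiplier for the parent's sex.
#' @return list(alleles, co_bp (sorted), origin (1 = hapA, 2 = hapB per
#'   site)).
#' @export
simulate_gamete <- function(hapA, hapB, map_chrom, sex_scale = 1) {
  .stop_if(nrow(map_chrom) == 0, "no markers on chromosome")
  .stop_if(length(hapA) != nrow(map_chrom) ||
             length(hapB) != nrow(map_chrom),
           "haplotype length must match marker count")
  cm_len <- max(map_chrom$cM) - min(map_chrom$cM)
  n_co <- stats::rpois(1, cm_len / 100 * sex_scale)
  co_cm <- sort(stats::runif(n_co, min(map_chrom$cM), max(map_chrom$cM)))
  co_bp <- if (n_co > 0) {
    cm_to_bp(map_chrom, map_chrom$chrom[1], co_cm)
  } else numeric(0)
  start <- sample.int(2L, 1L)
  k <- findInterval(map_chrom$bp, co_bp)
  origin <- 1L + (start - 1L + k) %% 2L
  list(alleles = ifelse(origin == 1L, hapA, hapB),
       co_bp = co_bp, origin = origin)
}

#' Simulate a pedigree genotype data set with full ground truth
#'
#' Simulates founder haplotypes, forms trio and duo offspring by Poisson
#' recombination over the genetic map (duo offspring get one genotyped
#' founder parent; the other parent is an unnamed, ungenotyped haplotype pair
#' drawn like a founder), then derives observed genotypes by applying
#' genotyping error and missingness to the truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{"sim_truth"}: list with elements
#'   \code{truth} (fully phased \code{\link{haplotype_set}}, hapA = paternal
#'   for offspring), \code{observed} (\code{\link{genotype_matrix}}),
#'   \code{pedigree}, \code{map}, \code{co_log} (data.frame parent,
#'   offspring, chrom, bp), \code{meioses}, \code{artifact} (per-variant
#'   flag, all FALSE here), \code{corruption_log} (NULL), \code{map_error_log}
#'   (NULL), \code{config}.
#' @export
simulate_dataset <- function(config) {
  cfg <- config
  .with_seed(cfg$seed, {
    map <- .sim_map(cfg)
    freqs <- .draw_freqs(cfg$allele_freq, nrow(map))
    founders <- simulate_founder_haplotypes(cfg, cfg$n_founders, map = map,
                                            freqs = freqs, seed = NULL)
    f_ids <- founders$sample_ids
    f_sex <- rep(c("male", "female"), length.out = cfg$n_founders)
    males <- f_ids[f_sex == "male"]; females <- f_ids[f_sex == "female"]
    .stop_if(length(males) == 0 || length(females) == 0,
             "need at least one male and one female founder")

    n_off <- cfg$n_trios + cfg$n_duos
    off_ids <- c(sprintf("T%03d", seq_len(cfg$n_trios)),
                 if (cfg$n_duos > 0) sprintf("D%03d", seq_len(cfg$n_duos)))
    sire <- dam <- rep(NA_character_, n_off)
    if (cfg$n_trios > 0) {
      sire[seq_len(cfg$n_trios)] <- sample(males, cfg$n_trios, replace = TRUE)
      dam[seq_len(cfg$n_trios)] <- sample(females, cfg$n_trios,
                                          replace = TRUE)
    }
    duo_roles <- character(0)
    if (cfg$n_duos > 0) {
      duo_idx <- cfg$n_trios + seq_len(cfg$n_duos)
      duo_roles <- sample(c("sire", "dam"), cfg$n_duos, replace = TRUE)
      sire[duo_idx] <- ifelse(duo_roles == "sire",
                              sample(males, cfg$n_duos, replace = TRUE), NA)
      dam[duo_idx] <- ifelse(duo_roles == "dam",
                             sample(females, cfg$n_duos, replace = TRUE), NA)
    }
    off_sex <- sample(c("male", "female"), n_off, replace = TRUE)

    n_site <- nrow(map)
    hapA <- cbind(founders$hapA,
                  matrix(0L, n_site, n_off, dimnames = list(NULL, off_ids)))
    hapB <- cbind(founders$hapB,
                  matrix(0L, n_site, n_off, dimnames = list(NULL, off_ids)))
    chrom_split <- split(seq_len(n_site), map$chrom)[unique(map$chrom)]
    scale <- cfg$sex_rate_scale

    co_rows <- list()
    hidden_pair <- function() {
      # ungenotyped parent of a duo offspring: fresh founder-style diplotype
      H <- .sim_founder_matrix(freqs, 2L, map$chrom, cfg$ld_copy_prob)
      list(hapA = H[, 1], hapB = H[, 2])
    }
    for (j in seq_len(n_off)) {
      oid <- off_ids[j]
      pat <- list(id = sire[j], sex = "male")
      mat <- list(id = dam[j], sex = "female")
      hidden <- if (is.na(sire[j]) || is.na(dam[j])) hidden_pair() else NULL
      for (side in c("pat", "mat")) {
        p <- if (side == "pat") pat else mat
        col <- if (!is.na(p$id)) match(p$id, f_ids) else NA
        for (ch in names(chrom_split)) {
          idx <- chrom_split[[ch]]
          if (!is.na(col)) {
            g <- simulate_gamete(founders$hapA[idx, col],
                                 founders$hapB[idx, col],
                                 map[idx, ], scale[[p$sex]])
            if (length(g$co_bp) > 0) {
              co_rows[[length(co_rows) + 1]] <-
                data.frame(parent = p$id, offspring = oid, chrom = ch,
                           bp = g$co_bp, stringsAsFactors = FALSE)
            }
          } else {
            g <- simulate_gamete(hidden$hapA[idx], hidden$hapB[idx],
                                 map[idx, ], scale[[p$sex]])
          }
          if (side == "pat") hapA[idx, cfg$n_founders + j] <- g$alleles
          else hapB[idx, cfg$n_founders + j] <- g$alleles
        }
      }
    }

    all_ids <- c(f_ids, off_ids)
    ped <- pedigree(id = all_ids,
                    sire = c(rep(NA, cfg$n_founders), sire),
                    dam = c(rep(NA, cfg$n_founders), dam),
                    sex = c(f_sex, off_sex))
    truth <- haplotype_set(map$chrom, map$bp, all_ids, hapA, hapB,
                           matrix(TRUE, n_site, length(all_ids)))

    g <- hapA + hapB
    n_cell <- length(g)
    if (cfg$genotype_error_rate > 0) {
      err <- stats::runif(n_cell) < cfg$genotype_error_rate
      shift <- sample.int(2L, n_cell, replace = TRUE)
      g[err] <- (g[err] + shift[err]) %% 3L
    }
    if (cfg$missing_rate > 0) {
      g[stats::runif(n_cell) < cfg$missing_rate] <- NA_integer_
    }
    observed <- genotype_matrix(map$chrom, map$bp, all_ids, g)

    co_log <- if (length(co_rows) > 0) do.call(rbind, co_rows) else
      data.frame(parent = character(), offspring = character(),
                 chrom = character(), bp = numeric(),
                 stringsAsFactors = FALSE)
    po <- parent_offspring_pairs(ped, all_ids)
    meioses <- data.frame(parent = po$parent, offspring = po$offspring,
                          parent_sex = ped$sex[match(po$parent, ped$id)],
                          stringsAsFactors = FALSE)
    structure(list(truth = truth, observed = observed, pedigree = ped,
                   map = map, co_log = co_log, meioses = meioses,
                   artifact = rep(FALSE, n_site), corruption_log = NULL,
                   map_error_log = NULL, config = cfg),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: ", length(x$truth$sample_ids), " individuals, ",
      length(x$truth$pos), " variants on ",
      length(unique(x$truth$chrom)), " chromosome(s)\n", sep = "")
  tr <- find_trios(x$pedigree, x$truth$sample_ids)
  du <- find_duos(x$pedigree, x$truth$sample_ids)
  cat("  trios:", nrow(tr), " duos:", nrow(du),
      " crossovers logged:", nrow(x$co_log), "\n")
  if (any(x$artifact)) cat("  artifact variants:", sum(x$artifact), "\n")
  invisible(x)
}

#' Simulate a per-window sequencing-depth track
#'
#' Lognormal window depths per sample around a per-sample mean; a simple
#' stand-in for real depth summaries used to exercise high-coverage-region
#' flagging.
#'
#' @param chrom_lengths named vector of chromosome bp lengths.
#' @param window_bp window size.
#' @param sample_ids samples to simulate.
#' @param mean_depth per-sample mean depth (recycled).
#' @param sdlog lognormal sd on the log scale.
#' @param seed integer seed.
#' @return data.frame(chrom, start, end, sample, depth), BED-style 0-based
#'   half-open windows.
#' @export
simulate_depth_track <- function(chrom_lengths, window_bp = 1e5,
                                 sample_ids, mean_depth = 25,
                                 sdlog = 0.2, seed = 1L) {
  .with_seed(seed, {
    mean_depth <- rep_len(mean_depth, length(sample_ids))
    rows <- list()
    for (k in seq_along(chrom_lengths)) {
      ch <- names(chrom_lengths)[k]
      starts <- seq(0, chrom_lengths[k] - 1, by = window_bp)
      ends <- pmin(starts + window_bp, chrom_lengths[k])
      for (s in seq_along(sample_ids)) {
        d <- stats::rlnorm(length(starts),
                           log(mean_depth[s]) - sdlog^2 / 2, sdlog)
        rows[[length(rows) + 1]] <-
          data.frame(chrom = ch, start = starts, end = ends,
                     sample = sample_ids[s], depth = d,
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
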