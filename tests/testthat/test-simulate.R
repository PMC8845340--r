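# Pedigree genotype simulator: determinism, marginal distributions,
# transmission structure, corruption machinery

test_that("simulation is bitwise deterministic under a seed", {
  s1 <- small_sim(seed = 99)
  s2 <- small_sim(seed = 99)
  expect_identical(s1$truth$hapA, s2$truth$hapA)
  expect_identical(s1$observed$calls, s2$observed$calls)
  expect_identical(s1$co_log, s2$co_log)
  s3 <- small_sim(seed = 100)
  expect_false(identical(s1$observed$calls, s3$observed$calls))
})

test_that("founder alleles follow the frequency model", {
  cfg <- sim_config(n_chrom = 1, n_variants_per_chrom = 1e4,
                    allele_freq = 1, n_founders = 4, n_trios = 0,
                    n_duos = 0, seed = 1)
  h <- simulate_founder_haplotypes(cfg)
  expect_true(all(h$hapA == 1L) && all(h$hapB == 1L))

  cfg <- sim_config(n_chrom = 1, n_variants_per_chrom = 1e4,
                    allele_freq = 0.3, ld_copy_prob = 0, n_founders = 5,
                    n_trios = 0, n_duos = 0, seed = 2)
  h <- simulate_founder_haplotypes(cfg)
  n_draw <- 1e4 * 10
  f_hat <- mean(cbind(h$hapA, h$hapB))
  se <- sqrt(0.3 * 0.7 / n_draw)
  expect_lt(abs(f_hat - 0.3), 3 * se)
})

test_that("gamete crossover counts follow the Poisson(map length) model", {
  map0 <- marker_map(rep("chr1", 50), paste0("m", 1:50),
                     rep(0, 50), seq(1e3, 5e4, length.out = 50))
  hapA <- rep(0L, 50); hapB <- rep(1L, 50)
  set.seed(4)
  for (i in 1:20) {
    g <- simulate_gamete(hapA, hapB, map0)   # 0-cM chromosome
    expect_length(g$co_bp, 0)
  }

  map1 <- marker_map(rep("chr1", 100), paste0("m", 1:100),
                     seq(0, 100, length.out = 100),
                     seq(1e4, 1e7, length.out = 100))
  set.seed(5)
  counts <- replicate(3000, length(simulate_gamete(rep(0L, 100),
                                                   rep(1L, 100),
                                                   map1)$co_bp))
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 3000))
})

test_that("a gamete is the parental mosaic defined by its crossovers", {
  map1 <- marker_map(rep("chr1", 200), paste0("m", 1:200),
                     seq(0, 100, length.out = 200),
                     seq(1e4, 1e7, length.out = 200))
  set.seed(6)
  hapA <- sample(0:1, 200, TRUE); hapB <- sample(0:1, 200, TRUE)
  found_one <- FALSE
  for (i in 1:50) {
    g <- simulate_gamete(hapA, hapB, map1)
    k <- findInterval(map1$bp, g$co_bp)
    start <- g$origin[1]
    expect_equal(g$origin, 1L + (start - 1L + k) %% 2L)
    expect_equal(g$alleles, ifelse(g$origin == 1L, hapA, hapB))
    if (length(g$co_bp) == 1) {
      found_one <- TRUE
      before <- map1$bp < g$co_bp
      expect_true(all(g$origin[before] == g$origin[1]))
      expect_true(all(g$origin[!before] == 3L - g$origin[1]))
    }
  }
  expect_true(found_one)
})

test_that("offspring haplotypes are parental mosaics with breaks at logged crossovers", {
  sim <- small_sim(seed = 41)
  tr <- find_trios(sim$pedigree, sim$truth$sample_ids)
  for (i in 1:3) {
    kid <- match(tr$offspring[i], sim$truth$sample_ids)
    sire <- match(tr$sire[i], sim$truth$sample_ids)
    for (ch in unique(sim$truth$chrom)) {
      idx <- which(sim$truth$chrom == ch)
      co <- sim$co_log[sim$co_log$offspring == tr$offspring[i] &
                         sim$co_log$parent == tr$sire[i] &
                         sim$co_log$chrom == ch, "bp"]
      k <- findInterval(sim$truth$pos[idx], sort(co))
      pat <- sim$truth$hapA[idx, kid]
      fromA <- pat == sim$truth$hapA[idx, sire]
      fromB <- pat == sim$truth$hapB[idx, sire]
      # within each inter-crossover segment the gamete sticks to one
      # parental haplotype (identifiable at sire-heterozygous sites)
      het <- sim$truth$hapA[idx, sire] != sim$truth$hapB[idx, sire]
      for (seg in unique(k)) {
        m <- k == seg & het
        if (sum(m) == 0) next
        expect_true(all(fromA[m]) || all(fromB[m]))
      }
    }
  }
})

test_that("genotyping error and missingness hit at the configured rates", {
  sim0 <- small_sim(seed = 51)
  expect_identical(sim0$observed$calls,
                   sim0$truth$hapA + sim0$truth$hapB)
  sim <- small_sim(seed = 52, genotype_error_rate = 0.01,
                   missing_rate = 0.05, n_variants_per_chrom = 500)
  truth_g <- sim$truth$hapA + sim$truth$hapB
  n <- length(truth_g)
  obs <- sim$observed$calls
  miss_hat <- mean(is.na(obs))
  expect_lt(abs(miss_hat - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  disc <- mean(obs != truth_g, na.rm = TRUE)
  expect_lt(abs(disc - 0.01), 3 * sqrt(0.01 * 0.99 / sum(!is.na(obs))))
})

test_that("error-free pedigrees contain no opposite-homozygote pairs", {
  sim <- small_sim(seed = 53)
  po <- phasebench:::parent_offspring_pairs(sim$pedigree,
                                            sim$observed$sample_ids)
  for (i in seq_len(nrow(po))) {
    a <- sim$observed$calls[, po$offspring[i]]
    b <- sim$observed$calls[, po$parent[i]]
    expect_equal(sum(abs(a - b) == 2L), 0)
  }
})

test_that("zero-rate corruption is the identity", {
  sim <- small_sim(seed = 61)
  out <- corrupt_haplotypes(sim$truth, 0, 0, 0, seed = 1)
  expect_identical(out$haplotypes$hapA, sim$truth$hapA)
  expect_identical(out$haplotypes$phased, sim$truth$phased)
  expect_equal(nrow(out$corruption_log), 0)
  expect_error(corrupt_haplotypes(sim$truth, -1, 0, 0), "non-negative")
})

test_that("long-switch breakpoints arrive at the configured Poisson rate", {
  pos <- seq.int(1e4, 1e8, length.out = 100)
  hs <- haplotype_set(rep(paste0("c", 1:100), each = 100),
                      rep(pos, 100), "S1",
                      hapA = matrix(0L, 1e4, 1),
                      hapB = matrix(1L, 1e4, 1),
                      phased = matrix(TRUE, 1e4, 1))
  out <- corrupt_haplotypes(hs, long_switch_rate_per_Mb = 0.05, seed = 3,
                            chrom_lengths = stats::setNames(
                              rep(1e8, 100), paste0("c", 1:100)))
  n_bk <- sum(out$corruption_log$type == "long_switch")
  expect_lt(abs(n_bk - 500), 3 * sqrt(500))
})

test_that("corruption swaps labels cumulatively and leaves genotypes alone", {
  sim <- small_sim(seed = 62)
  out <- corrupt_haplotypes(sim$truth, long_switch_rate_per_Mb = 0.5,
                            point_switch_rate_per_site = 0.01, seed = 4)
  expect_identical(out$haplotypes$hapA + out$haplotypes$hapB,
                   sim$truth$hapA + sim$truth$hapB)
  # verify the parity semantics for one sample-chromosome
  log1 <- out$corruption_log
  sid <- sim$truth$sample_ids[1]
  ch <- "chr1"
  idx <- which(sim$truth$chrom == ch)
  bk <- sort(log1$pos[log1$sample == sid & log1$chrom == ch &
                        log1$type == "long_switch"])
  pt <- log1$pos[log1$sample == sid & log1$chrom == ch &
                   log1$type == "point_switch"]
  flip <- (findInterval(sim$truth$pos[idx], bk) %% 2L == 1L)
  flip <- xor(flip, sim$truth$pos[idx] %in% pt)
  expect_equal(out$haplotypes$hapA[idx, sid],
               ifelse(flip, sim$truth$hapB[idx, sid],
                      sim$truth$hapA[idx, sid]))
})

test_that("unphasing removes the configured fraction of heterozygous sites", {
  sim <- small_sim(seed = 63)
  out <- corrupt_haplotypes(sim$truth, unphase_fraction = 0.25, seed = 5)
  het <- sim$truth$hapA != sim$truth$hapB
  lost <- sim$truth$phased & !out$haplotypes$phased
  expect_true(all(lost[!het] == FALSE))
  frac <- sum(lost) / sum(het)
  expect_lt(abs(frac - 0.25), 0.02)
})

test_that("artifact variants are flagged and distributed as configured", {
  sim <- small_sim(seed = 71)
  expect_identical(inject_artifact_variants(sim, 0), sim)
  simA <- inject_artifact_variants(sim, 50, mode = "iid_hwe", freq = 0.3,
                                   seed = 6)
  expect_equal(sum(simA$artifact), 50)
  expect_equal(length(simA$artifact), length(simA$observed$pos))
  g <- simA$observed$calls[simA$artifact, ]
  f_hat <- mean(g) / 2
  expect_lt(abs(f_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * length(g))))

  simH <- inject_artifact_variants(sim, 30, mode = "excess_het",
                                   freq = 0.3, seed = 7)
  gh <- simH$observed$calls[simH$artifact, ]
  expect_true(all(gh %in% 0:1))
  hw <- hwe_test(sum(gh == 0L), sum(gh == 1L), 0)
  expect_lt(hw$p, 0.05)
  expect_error(inject_artifact_variants(sim, -1), ">= 0")
})

test_that("map-error injection relocates coordinates without touching data", {
  sim <- small_sim(seed = 81)
  expect_identical(inject_map_errors(sim, 2e5, 0), sim)
  simM <- inject_map_errors(sim, 5e5, 4e6, chrom = "chr1",
                            block_start_bp = 1e6, seed = 8)
  log <- simM$map_error_log
  expect_equal(nrow(log), 1)
  # destination lands near the offset target (up to the splice shift of
  # about one block span plus one marker gap)
  expect_lt(abs((log$new_start - log$orig_start) - 4e6), 7e5)
  expect_equal(sort(paste(simM$observed$chrom, simM$observed$calls[, 1])),
               sort(paste(sim$observed$chrom, sim$observed$calls[, 1])))
  # genotype rows moved with their coordinates, order preserved
  moved <- which(sim$observed$chrom == "chr1" &
                   sim$observed$pos >= log$orig_start &
                   sim$observed$pos <= log$orig_end)
  new_at <- which(simM$observed$chrom == "chr1" &
                    simM$observed$pos >= log$new_start &
                    simM$observed$pos <= log$new_end)
  expect_equal(length(new_at), log$n_markers)
  expect_equal(simM$observed$calls[new_at, ],
               sim$observed$calls[moved, ])
})
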