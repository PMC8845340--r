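# Switch errors, QA blocks, QAN, genome fractions, pairwise accuracy

test_that("informative sites require truth het+phase and genotype concordance", {
  truth <- make_het_truth(c(10L, 20L, 30L, 40L), c(0L, 1L, 0L, 1L))
  inf <- truth
  r <- informative_sites(truth, inf, "S1", "chr1")
  expect_equal(r$index, 1:4)

  truth2 <- truth; truth2$phased[2, 1] <- FALSE
  r <- informative_sites(truth2, inf, "S1", "chr1")
  expect_equal(r$index, c(1, 3, 4))

  inf2 <- inf; inf2$hapA[3, 1] <- 1L  # genotype now 2, discordant
  r <- informative_sites(truth, inf2, "S1", "chr1")
  expect_equal(r$index, c(1, 2, 4))
  expect_equal(r$n_discordant, 1)
  expect_error(informative_sites(truth, inf, "nobody", "chr1"), "absent")
})

test_that("phasing yield counts inferred-phased informative sites", {
  expect_equal(phasing_yield(100, 97), 0.97)
  expect_equal(phasing_yield(10, 10), 1)
  expect_true(is.na(phasing_yield(0, 0)))

  pos <- seq_len(5e4) * 100
  truth <- make_het_truth(pos, rep(c(0L, 1L), length.out = 5e4))
  out <- corrupt_haplotypes(truth, unphase_fraction = 0.02, seed = 12)
  pr <- count_switch_errors(truth, out$haplotypes, "S1", "chr1")
  expect_equal(pr$yield, 0.98, tolerance = 1e-4)
})

test_that("switch counting matches the paired-combination definition", {
  pos <- as.integer(seq_len(100) * 1000)
  hapA <- rep(c(0L, 1L), 50)
  truth <- make_het_truth(pos, hapA)

  pr <- count_switch_errors(truth, truth, "S1", "chr1")
  expect_equal(pr$sec, 0L)
  expect_equal(pr$ser, 0)

  # a single internal flipped marker produces two consecutive switch errors
  inf <- flip_sites(truth, "S1", 50)
  pr <- count_switch_errors(truth, inf, "S1", "chr1")
  expect_equal(pr$sec, 2L)

  # one clean break produces one switch error
  inf <- flip_sites(truth, "S1", 51:100)
  pr <- count_switch_errors(truth, inf, "S1", "chr1")
  expect_equal(pr$sec, 1L)
  expect_equal(pr$ser, 1 / 100)
})

test_that("switch counts equal the brute-force oracle on random instances", {
  set.seed(13)
  for (rep in 1:300) {
    n <- sample(2:12, 1)
    hapA_t <- sample(0:1, n, TRUE)
    flips <- sample(c(TRUE, FALSE), n, TRUE)
    compared <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.8, 0.2))
    truth <- make_het_truth(as.integer(seq_len(n) * 10), hapA_t)
    inf <- flip_sites(truth, "S1", which(flips))
    inf$phased[!compared, 1] <- FALSE
    pr <- count_switch_errors(truth, inf, "S1", "chr1")
    hapA_i <- ifelse(flips, 1L - hapA_t, hapA_t)
    expect_equal(pr$sec, oracle_sec(hapA_t, hapA_i, compared))
  }
})

test_that("unphased sites are skipped without breaking the switch chain", {
  pos <- as.integer(seq_len(10) * 10)
  truth <- make_het_truth(pos, rep(0L, 10))
  inf <- flip_sites(truth, "S1", 6:10)
  inf$phased[5:6, 1] <- FALSE   # the orientation change is site 4 -> 7
  pr <- count_switch_errors(truth, inf, "S1", "chr1")
  expect_equal(pr$sec, 1L)
  expect_equal(pr$n_compared, 8)
})

test_that("blocks split at switches and carry local QA multipliers", {
  pos <- as.integer(seq(0, 1e7, length.out = 101) + 1)
  truth <- make_het_truth(pos, rep(0L, 101))

  b <- build_blocks(count_switch_errors(truth, truth, "S1", "chr1"))
  expect_equal(nrow(b), 1)
  expect_equal(b$raw_len, pos[101] - pos[1])
  expect_equal(b$qa_len, b$raw_len)

  inf <- flip_sites(truth, "S1", 51:101)
  b <- build_blocks(count_switch_errors(truth, inf, "S1", "chr1"))
  expect_equal(nrow(b), 2)
  expect_equal(b$raw_len, c(pos[50] - pos[1], pos[101] - pos[51]),
               tolerance = 1e-12)
  expect_true(all(abs(b$raw_len - 5e6) < 2e5))

  # half the sites of one block unphased halves its QA length
  inf2 <- truth
  inf2$phased[seq(1, 101, by = 2), 1] <- FALSE
  b <- build_blocks(count_switch_errors(truth, inf2, "S1", "chr1"))
  expect_equal(b$qa_len, b$raw_len * b$n_phased / b$n_info)
  expect_lt(abs(b$qa_len / b$raw_len - 0.5), 0.01)

  # global-yield variant uses the chromosome-wide yield
  bg <- build_blocks(count_switch_errors(truth, inf2, "S1", "chr1"),
                     global_yield = TRUE)
  expect_equal(bg$qa_len, bg$raw_len * (50 / 101))
})

test_that("QAN50 follows its definition and the threshold-scan oracle", {
  blocks <- data.frame(individual = "S1", chrom = "chr1",
                       first_bp = c(0, 0), last_bp = c(6e6, 4e6),
                       n_info = c(60L, 40L), n_phased = c(60L, 40L),
                       raw_len = c(6e6, 4e6), qa_len = c(6e6, 4e6))
  q <- qan_curve(blocks)
  expect_equal(q$qan50, 6e6)

  one <- blocks[1, ]
  expect_equal(qan_curve(one)$qan50, one$qa_len)

  set.seed(14)
  for (rep in 1:100) {
    k <- sample(1:20, 1)
    b <- data.frame(individual = "S1", chrom = "chr1",
                    first_bp = 0, last_bp = 0,
                    n_info = sample(1:50, k, TRUE),
                    n_phased = 0L, raw_len = 0,
                    qa_len = round(runif(k, 0, 1e7)))
    q <- qan_curve(b)
    expect_equal(q$qan50, oracle_qan50(b$qa_len, b$n_info))
  }
})

test_that("QANx is non-increasing in x and drops when a switch is added", {
  pos <- as.integer(seq(0, 1e7, length.out = 201) + 1)
  truth <- make_het_truth(pos, rep(0L, 201))
  q0 <- qan_curve(build_blocks(count_switch_errors(truth, truth, "S1",
                                                   "chr1")))
  expect_true(all(diff(q0$curve$qan_bp) <= 0))
  inf <- flip_sites(truth, "S1", 101:201)
  q1 <- qan_curve(build_blocks(count_switch_errors(truth, inf, "S1",
                                                   "chr1")))
  expect_lte(q1$qan50, q0$qan50)
})

test_that("genome fractions match hand computation on a 3-block chromosome", {
  blocks <- data.frame(individual = "S1", chrom = "chr1",
                       first_bp = c(1, 4e6 + 1, 9e6 + 1),
                       last_bp = c(4e6, 9e6, 10e6),
                       n_info = c(40L, 50L, 10L),
                       n_phased = c(40L, 50L, 10L),
                       raw_len = c(4e6 - 1, 5e6 - 1, 1e6 - 1),
                       qa_len = c(4e6 - 1, 5e6 - 1, 1e6 - 1))
  gf <- genome_fraction_in_blocks(blocks, thresholds_bp = c(1e6, 4.5e6,
                                                            2e7))
  span <- 10e6 - 1
  # the 1e6-1 block is just below the 1 Mb threshold and drops out
  expect_equal(gf$fraction,
               c((4e6 - 1 + 5e6 - 1) / span,
                 (5e6 - 1) / span,
                 0))
  one <- blocks[1, ]
  expect_equal(genome_fraction_in_blocks(one, 1e6)$fraction, 1)
  expect_error(genome_fraction_in_blocks(blocks, -1), "positive")
})

test_that("pairwise accuracy matches exhaustive enumeration around one switch", {
  pos <- as.integer(seq_len(100) * 1e4)
  truth <- make_het_truth(pos, rep(0L, 100))
  inf <- flip_sites(truth, "S1", 51:100)
  pr <- count_switch_errors(truth, inf, "S1", "chr1")
  d <- c(1e5, 5e5)
  got <- pairwise_accuracy(list(pr), distances_bp = d, tolerance = 0.001,
                           exact = TRUE)
  # enumeration oracle over all site pairs
  for (k in seq_along(d)) {
    ok <- tot <- 0
    for (i in 1:99) for (j in (i + 1):100) {
      sep <- pos[j] - pos[i]
      if (abs(sep - d[k]) <= d[k] * 0.001) {
        tot <- tot + 1
        ok <- ok + ((i <= 50) == (j <= 50))
      }
    }
    expect_equal(got$prob[k], ok / tot)
    expect_equal(got$n_pairs[k], tot)
  }
  perfect <- pairwise_accuracy(
    list(count_switch_errors(truth, truth, "S1", "chr1")),
    distances_bp = d, exact = TRUE)
  expect_equal(perfect$prob, c(1, 1))
  expect_warning(
    pairwise_accuracy(list(pr), distances_bp = 1e9, exact = TRUE),
    "no pairs")
})

test_that("sampled pairwise accuracy agrees with the exact computation", {
  set.seed(15)
  pos <- as.integer(sort(sample.int(1e7, 2000)))
  truth <- make_het_truth(pos, sample(0:1, 2000, TRUE))
  out <- corrupt_haplotypes(truth, long_switch_rate_per_Mb = 0.5, seed = 16)
  pr <- count_switch_errors(truth, out$haplotypes, "S1", "chr1")
  d <- c(1e5, 1e6)
  ex <- pairwise_accuracy(list(pr), distances_bp = d, exact = TRUE)
  sm <- pairwise_accuracy(list(pr), distances_bp = d, max_pairs = 2e4,
                          seed = 2)
  expect_lt(max(abs(ex$prob - sm$prob)), 0.05)
})
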