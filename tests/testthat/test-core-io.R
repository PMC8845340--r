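# VCF / FAM / map / BED readers and writers, and trio-duo discovery

vcf_lines <- function(rows, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows)
}

test_that("genotype codes follow the alternate-allele count convention", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/1\t1|1",
    "chr1\t200\t.\tG\tT\t.\t.\t.\tGT\t./.\t0/0",
    "chr1\t300\t.\tG\tT\t.\t.\t.\tGT\t.\t1/0")), f)
  gm <- read_genotypes(f)
  expect_equal(gm$calls[, "S1"], c(1L, NA, NA))
  expect_equal(gm$calls[, "S2"], c(2L, 0L, 1L))
  expect_equal(gm$pos, c(100L, 200L, 300L))
})

test_that("non-SNP and multi-allelic records are skipped with a message", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0",
    "chr1\t150\t.\tAT\tA\t.\t.\t.\tGT\t0/1\t0/0",
    "chr1\t180\t.\tA\tC,G\t.\t.\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tG\tT\t.\t.\t.\tGT\t1/1\t0/1")), f)
  expect_message(gm <- read_genotypes(f), "2 non-biallelic-SNP")
  expect_equal(gm$pos, c(100L, 200L))
})

test_that("duplicate positions on a chromosome are rejected", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0",
    "chr1\t100\t.\tG\tT\t.\t.\t.\tGT\t1/1\t0/1")), f)
  expect_error(read_genotypes(f), "duplicate position")
})

test_that("phase status follows the separator and allele completeness", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t1|0\t0/1",
    "chr1\t200\t.\tG\tT\t.\t.\t.\tGT\t.|1\t1|1")), f)
  hs <- read_haplotypes(f)
  expect_equal(unname(hs$hapA[1, "S1"]), 1L)
  expect_equal(unname(hs$hapB[1, "S1"]), 0L)
  expect_true(hs$phased[1, "S1"])
  expect_false(hs$phased[1, "S2"])   # `/` separator
  expect_false(hs$phased[2, "S1"])   # missing allele inside `|`
  expect_true(hs$phased[2, "S2"])
})

test_that("phased-record count matches construction on a mixed file", {
  set.seed(5)
  n <- 20
  sep <- sample(c("|", "/"), n, replace = TRUE)
  a1 <- sample(0:1, n, replace = TRUE)
  a2 <- sample(0:1, n, replace = TRUE)
  rows <- sprintf("chr1\t%d\t.\tA\tC\t.\t.\t.\tGT\t%d%s%d",
                  seq_len(n) * 10, a1, sep, a2)
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(rows, samples = "S1"), f)
  hs <- read_haplotypes(f)
  expect_equal(sum(hs$phased), sum(sep == "|"))
})

test_that("genotype and haplotype VCF round-trips are exact", {
  set.seed(42)
  n <- 50; m <- 6
  calls <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
  gm <- genotype_matrix(rep("chr1", n), sort(sample.int(1e6, n)),
                        paste0("S", 1:m), calls)
  f <- tempfile(fileext = ".vcf")
  write_genotypes(gm, f)
  gm2 <- read_genotypes(f)
  expect_identical(gm2$calls, gm$calls)
  expect_identical(gm2$pos, gm$pos)

  hapA <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  hapB <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  phased <- matrix(sample(c(TRUE, FALSE), n * m, replace = TRUE), n, m)
  hs <- haplotype_set(rep("chr1", n), gm$pos, paste0("S", 1:m),
                      hapA, hapB, phased)
  f2 <- tempfile(fileext = ".vcf")
  write_haplotypes(hs, f2)
  hs2 <- read_haplotypes(f2)
  expect_identical(hs2$hapA, hs$hapA)
  expect_identical(hs2$hapB, hs$hapB)
  expect_identical(hs2$phased, hs$phased)
})

test_that("fully phased and unphased sites are written with | and /", {
  hs <- haplotype_set("chr1", c(10L, 20L, 30L), "S1",
                      hapA = matrix(c(0L, 1L, 1L)),
                      hapB = matrix(c(1L, 0L, 1L)),
                      phased = matrix(c(TRUE, TRUE, FALSE)))
  f <- tempfile(fileext = ".vcf")
  write_haplotypes(hs, f)
  body <- grep("^chr", readLines(f), value = TRUE)
  gt <- vapply(strsplit(body, "\t"), `[`, "", 10)
  expect_equal(gt, c("0|1", "1|0", "1/1"))
})

test_that("trio and duo discovery follows parental genotype availability", {
  ped <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                  dam = c(NA, NA, "B"))
  tr <- find_trios(ped, c("A", "B", "C"))
  expect_equal(nrow(tr), 1)
  expect_equal(unlist(tr[1, ]), c(offspring = "C", sire = "A", dam = "B"))
  expect_equal(nrow(find_duos(ped, c("A", "B", "C"))), 0)

  du <- find_duos(ped, c("A", "C"))  # B not genotyped
  expect_equal(nrow(find_trios(ped, c("A", "C"))), 0)
  expect_equal(du$offspring, "C")
  expect_equal(du$parent, "A")
})

test_that("trios and duos partition offspring with a genotyped parent", {
  sim <- small_sim()
  ids <- sim$observed$sample_ids
  tr <- find_trios(sim$pedigree, ids)
  du <- find_duos(sim$pedigree, ids)
  expect_equal(nrow(tr), 8)
  expect_equal(nrow(du), 4)
  expect_length(intersect(tr$offspring, du$offspring), 0)
  po <- unique(phasebench:::parent_offspring_pairs(sim$pedigree,
                                                   ids)$offspring)
  expect_setequal(po, c(tr$offspring, du$offspring))
})

test_that("FAM round-trip preserves pedigree structure and sex", {
  sim <- small_sim()
  f <- tempfile(fileext = ".fam")
  write_pedigree(sim$pedigree, f)
  ped2 <- read_pedigree(f)
  expect_equal(ped2$id, sim$pedigree$id)
  expect_equal(ped2$sire, sim$pedigree$sire)
  expect_equal(ped2$dam, sim$pedigree$dam)
  expect_equal(ped2$sex, sim$pedigree$sex)
})

test_that("pedigree cycles are rejected", {
  expect_error(pedigree(id = c("A", "B"), sire = c("B", "A"),
                        dam = c(NA, NA)),
               "cycle")
})

test_that("marker map round-trips and validates cM monotonicity", {
  m <- marker_map(rep("chr1", 3), paste0("m", 1:3), c(0, 0.5, 2),
                  c(100L, 5000L, 9000L))
  f <- tempfile(fileext = ".map")
  write_marker_map(m, f)
  m2 <- read_marker_map(f)
  expect_equal(m2$bp, m$bp)
  expect_equal(m2$cM, m$cM)
  expect_error(marker_map("chr1", c("a", "b"), c(2, 1), c(10L, 20L)),
               "non-decreasing")
})

test_that("region masks merge, cover and round-trip through BED", {
  m <- region_mask(c("chr1", "chr1", "chr2"), c(10, 15, 0), c(20, 30, 5))
  expect_equal(nrow(m), 2)          # chr1 intervals merged
  expect_equal(m$end[m$chrom == "chr1"], 30)
  expect_true(mask_covers(m, "chr1", 11))
  expect_true(mask_covers(m, "chr1", 30))   # 1-based 30 -> 0-based 29
  expect_false(mask_covers(m, "chr1", 31))
  expect_false(mask_covers(m, "chr1", 10))  # 1-based 10 -> 0-based 9
  f <- tempfile(fileext = ".bed")
  write_bed(m, f)
  m2 <- read_bed(f)
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)
})
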