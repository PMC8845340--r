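# VCF input/output (GT field only). Parsing is delegated to vcfR; writing is
# a minimal VCFv4.2 formatter since only GT is ever emitted.

.parse_vcf <- function(vcf_source) {
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  }
  chrom <- fix[snp, "CHROM"]
  pos <- as.integer(fix[snp, "POS"])
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    .stop_if(anyDuplicated(p) > 0,
             "duplicate position on chromosome '", ch, "'")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(snp),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  list(chrom = chrom, pos = pos, sample_ids = colnames(gt), gt = gt,
       n_skipped = n_skip)
}

# decode GT strings via a lookup over the distinct strings present
.decode_gt <- function(gt) {
  u <- unique(as.vector(gt))
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", u)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", u)
  diploid <- grepl("[/|]", u)
  a1[!diploid] <- NA; a2[!diploid] <- NA
  to_int <- function(a) {
    x <- suppressWarnings(as.integer(a))
    x[!is.na(x) & !(x %in% 0:1)] <- NA
    x
  }
  i1 <- to_int(a1); i2 <- to_int(a2)
  sep_phased <- grepl("|", u, fixed = TRUE)
  idx <- match(gt, u)
  list(a1 = matrix(i1[idx], nrow = nrow(gt)),
       a2 = matrix(i2[idx], nrow = nrow(gt)),
       phased = matrix(sep_phased[idx], nrow = nrow(gt)))
}

#' Read genotypes from a VCF file
#'
#' Only biallelic SNP records are retained (others are skipped with a
#' message); genotypes are coded by alternate-allele count, with \code{./.}
#' and half-missing calls read as missing. Phase separators are ignored.
#'
#' @param vcf_source path to a VCF file (plain or gzipped).
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(vcf_source) {
  p <- .parse_vcf(vcf_source)
  d <- .decode_gt(p$gt)
  calls <- d$a1 + d$a2
  genotype_matrix(p$chrom, p$pos, p$sample_ids, calls)
}

#' Read haplotypes from a phased VCF file
#'
#' A site is phase-known iff its GT separator is \code{|} and both alleles
#' are non-missing. \code{hapA} is the left allele of the GT field.
#'
#' @inheritParams read_genotypes
#' @return A \code{\link{haplotype_set}}.
#' @export
read_haplotypes <- function(vcf_source) {
  p <- .parse_vcf(vcf_source)
  d <- .decode_gt(p$gt)
  haplotype_set(p$chrom, p$pos, p$sample_ids,
                hapA = d$a1, hapB = d$a2,
                phased = d$phased & !is.na(d$a1) & !is.na(d$a2))
}

.vcf_header <- function(sample_ids, chroms, chrom_lengths = NULL) {
  contigs <- if (is.null(chrom_lengths)) {
    paste0("##contig=<ID=", chroms, ">")
  } else {
    paste0("##contig=<ID=", chroms, ",length=", chrom_lengths[chroms], ">")
  }
  c("##fileformat=VCFv4.2",
    contigs,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

#' Write a haplotype set to a VCF file
#'
#' Phased sites are emitted with the \code{|} separator, unphased sites with
#' \code{/}; missing alleles as \code{.}. Reading the file back with
#' \code{\link{read_haplotypes}} reproduces the input.
#'
#' @param hs a \code{\link{haplotype_set}}.
#' @param path output file path.
#' @param chrom_lengths optional named vector of chromosome lengths for the
#'   contig header lines.
#' @return \code{path}, invisibly.
#' @export
write_haplotypes <- function(hs, path, chrom_lengths = NULL) {
  a1 <- ifelse(is.na(hs$hapA), ".", as.character(hs$hapA))
  a2 <- ifelse(is.na(hs$hapB), ".", as.character(hs$hapB))
  sep <- ifelse(hs$phased, "|", "/")
  gt <- matrix(paste0(a1, sep, a2), nrow = nrow(hs$hapA))
  .write_vcf_gt(hs$chrom, hs$pos, gt, hs$sample_ids, path, chrom_lengths)
}

#' Write a genotype matrix to a VCF file (unphased)
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @inheritParams write_haplotypes
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(gm, path, chrom_lengths = NULL) {
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(ifelse(is.na(gm$calls), "./.", code[as.character(gm$calls)]),
               nrow = nrow(gm$calls))
  .write_vcf_gt(gm$chrom, gm$pos, gt, gm$sample_ids, path, chrom_lengths)
}

.write_vcf_gt <- function(chrom, pos, gt, sample_ids, path,
                          chrom_lengths = NULL) {
  gt_cols <- lapply(seq_len(ncol(gt)), function(j) gt[, j])
  gt_str <- do.call(paste, c(gt_cols, sep = "\t"))
  body <- paste(chrom, pos, ".", "A", "C", ".", ".", ".", "GT",
                gt_str, sep = "\t")
  writeLines(c(.vcf_header(sample_ids, unique(chrom), chrom_lengths), body),
             path)
  invisible(path)
}
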