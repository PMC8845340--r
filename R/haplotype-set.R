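#' Construct a haplotype set
#'
#' Per-sample pairs of allele sequences with a per-site phase-known mask.
#' Where \code{phased} is \code{TRUE}, \code{hapA + hapB} equals the genotype
#' code; where it is \code{FALSE} the A/B order carries no meaning (the allele
#' pair still encodes the unphased genotype).
#'
#' @param chrom,pos,sample_ids variant axis and samples, as in
#'   \code{\link{genotype_matrix}}.
#' @param hapA,hapB integer matrices (variants x samples) with entries in
#'   \{0, 1, NA\}.
#' @param phased logical matrix (variants x samples); sites with a missing
#'   allele are forced to \code{FALSE}.
#' @return An object of class \code{"haplotype_set"}.
#' @export
haplotype_set <- function(chrom, pos, sample_ids, hapA, hapB, phased) {
  hapA <- as.matrix(hapA); hapB <- as.matrix(hapB); phased <- as.matrix(phased)
  chrom <- rep_len(as.character(chrom), nrow(hapA))
  pos <- as.integer(pos)
  sample_ids <- as.character(sample_ids)
  .stop_if(!all(dim(hapA) == dim(hapB)) || !all(dim(hapA) == dim(phased)),
           "hapA, hapB and phased must have identical dimensions")
  .stop_if(length(chrom) != nrow(hapA) || length(pos) != nrow(hapA),
           "chrom/pos length must match nrow(hapA)")
  .stop_if(length(sample_ids) != ncol(hapA),
           "sample_ids length must match ncol(hapA)")
  .stop_if(anyDuplicated(sample_ids) > 0, "sample_ids must be unique")
  ok <- function(m) all(is.na(m) | m %in% 0:1)
  .stop_if(!ok(hapA) || !ok(hapB), "haplotype alleles must be 0, 1 or NA")
  o <- .variant_order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  hapA <- hapA[o, , drop = FALSE]; hapB <- hapB[o, , drop = FALSE]
  phased <- phased[o, , drop = FALSE]
  .check_positions(chrom, pos)
  # half-known phase is unusable: force unphased where an allele is missing
  phased <- phased & !is.na(hapA) & !is.na(hapB)
  storage.mode(hapA) <- "integer"; storage.mode(hapB) <- "integer"
  dimnames(hapA) <- dimnames(hapB) <- dimnames(phased) <-
    list(NULL, sample_ids)
  structure(list(chrom = chrom, pos = pos, sample_ids = sample_ids,
                 hapA = hapA, hapB = hapB, phased = phased),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$pos), "variants x",
      length(x$sample_ids), "samples on",
      length(unique(x$chrom)), "chromosome(s)\n")
  cat(sprintf("  phased fraction: %.4f\n", mean(x$phased)))
  invisible(x)
}

#' @export
dim.haplotype_set <- function(x) dim(x$hapA)

#' Genotypes implied by a haplotype set
#'
#' @param hs a \code{\link{haplotype_set}}.
#' @return A \code{\link{genotype_matrix}} with calls \code{hapA + hapB}
#'   (missing where either allele is missing).
#' @export
hap_genotypes <- function(hs) {
  genotype_matrix(hs$chrom, hs$pos, hs$sample_ids, hs$hapA + hs$hapB)
}

subset_hap_variants <- function(hs, idx) {
  if (is.logical(idx)) idx <- which(idx)
  structure(list(chrom = hs$chrom[idx], pos = hs$pos[idx],
                 sample_ids = hs$sample_ids,
                 hapA = hs$hapA[idx, , drop = FALSE],
                 hapB = hs$hapB[idx, , drop = FALSE],
                 phased = hs$phased[idx, , drop = FALSE]),
            class = class(hs))
}
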