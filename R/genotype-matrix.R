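#' Construct a genotype matrix
#'
#' Container for biallelic SNP genotypes coded as alternate-allele counts
#' (0, 1, 2; \code{NA} = missing) for variants (rows) by samples (columns).
#' Variants are stored sorted by chromosome and position; positions are
#' 1-based bp and must be strictly increasing within a chromosome.
#'
#' @param chrom character vector of chromosome identifiers, one per variant.
#' @param pos integer vector of 1-based bp positions, one per variant.
#' @param sample_ids character vector of unique sample identifiers.
#' @param calls integer matrix (variants x samples) with entries in
#'   \{0, 1, 2, NA\}.
#' @return An object of class \code{"genotype_matrix"}: a list with elements
#'   \code{chrom}, \code{pos}, \code{sample_ids}, \code{calls}.
#' @export
genotype_matrix <- function(chrom, pos, sample_ids, calls) {
  calls <- as.matrix(calls)
  chrom <- rep_len(as.character(chrom), nrow(calls))
  pos <- as.integer(pos)
  sample_ids <- as.character(sample_ids)
  .stop_if(length(chrom) != nrow(calls) || length(pos) != nrow(calls),
           "chrom/pos length must match nrow(calls)")
  .stop_if(length(sample_ids) != ncol(calls),
           "sample_ids length must match ncol(calls)")
  .stop_if(anyDuplicated(sample_ids) > 0, "sample_ids must be unique")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  .stop_if(any(bad), "genotype codes must be 0, 1, 2 or NA")
  o <- .variant_order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  calls <- calls[o, , drop = FALSE]
  .check_positions(chrom, pos)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(NULL, sample_ids)
  structure(list(chrom = chrom, pos = pos, sample_ids = sample_ids,
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$pos), "variants x",
      length(x$sample_ids), "samples on",
      length(unique(x$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# subset variants by a logical/integer index, preserving class
subset_variants <- function(gm, idx) {
  if (is.logical(idx)) idx <- which(idx)
  structure(list(chrom = gm$chrom[idx], pos = gm$pos[idx],
                 sample_ids = gm$sample_ids,
                 calls = gm$calls[idx, , drop = FALSE]),
            class = class(gm))
}

# per-variant alternate allele frequency over non-missing calls
allele_frequency <- function(gm) {
  n <- rowSums(!is.na(gm$calls))
  ifelse(n > 0, rowSums(gm$calls, na.rm = TRUE) / (2 * n), NA_real_)
}
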