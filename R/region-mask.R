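#' Construct a region mask
#'
#' A set of genomic intervals in 0-based half-open bp coordinates (BED
#' convention), stored merged and sorted. A 1-based marker position p lies
#' inside interval [start, end) iff start < p <= end.
#'
#' @param chrom,start,end interval vectors (0-based half-open).
#' @return An object of class \code{"region_mask"} (a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}).
#' @export
region_mask <- function(chrom = character(), start = numeric(),
                        end = numeric()) {
  .stop_if(any(end < start), "interval end must be >= start")
  .stop_if(any(start < 0), "intervals must have non-negative start")
  m <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), stringsAsFactors = FALSE)
  m <- m[m$end > m$start, , drop = FALSE]
  if (nrow(m) > 0) {
    m <- m[order(match(m$chrom, unique(m$chrom)), m$start, m$end), ]
    out <- list()
    for (ch in unique(m$chrom)) {
      x <- m[m$chrom == ch, ]
      s <- x$start; e <- x$end
      keep_s <- s[1]; keep_e <- e[1]
      if (nrow(x) > 1) {
        for (i in 2:nrow(x)) {
          k <- length(keep_s)
          if (s[i] <= keep_e[k]) {
            keep_e[k] <- max(keep_e[k], e[i])
          } else {
            keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
          }
        }
      }
      out[[ch]] <- data.frame(chrom = ch, start = keep_s, end = keep_e,
                              stringsAsFactors = FALSE)
    }
    m <- do.call(rbind, out)
  }
  rownames(m) <- NULL
  class(m) <- c("region_mask", "data.frame")
  m
}

#' Union of region masks
#'
#' @param ... \code{\link{region_mask}} objects (or data.frames with
#'   chrom/start/end columns).
#' @return A merged \code{\link{region_mask}}.
#' @export
mask_union <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(region_mask())
  all <- do.call(rbind, lapply(parts, function(x)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               stringsAsFactors = FALSE)))
  region_mask(all$chrom, all$start, all$end)
}

#' Test which 1-based positions fall inside a mask
#'
#' @param mask a \code{\link{region_mask}}.
#' @param chrom,pos vectors of chromosome and 1-based position.
#' @return Logical vector.
#' @export
mask_covers <- function(mask, chrom, pos) {
  hit <- rep(FALSE, length(pos))
  if (nrow(mask) == 0) return(hit)
  for (ch in unique(mask$chrom)) {
    iv <- mask[mask$chrom == ch, ]
    sel <- chrom == ch
    if (!any(sel)) next
    p0 <- pos[sel] - 1  # to 0-based point
    k <- findInterval(p0, iv$start)
    hit[sel] <- k > 0 & p0 < iv$end[pmax(k, 1)]
  }
  hit
}

#' Remove variants covered by a mask
#'
#' @param x a \code{\link{genotype_matrix}} or \code{\link{haplotype_set}}.
#' @param mask a \code{\link{region_mask}}.
#' @return Object of the same class with masked variants removed.
#' @export
apply_region_mask <- function(x, mask) {
  drop <- mask_covers(mask, x$chrom, x$pos)
  if (inherits(x, "genotype_matrix")) subset_variants(x, !drop)
  else subset_hap_variants(x, !drop)
}

#' Read a BED file as a region mask
#'
#' @param bed_source path to a 3+ column BED file.
#' @return A \code{\link{region_mask}}.
#' @export
read_bed <- function(bed_source) {
  x <- utils::read.table(bed_source, header = FALSE)
  region_mask(as.character(x[[1]]), as.numeric(x[[2]]), as.numeric(x[[3]]))
}

#' Write a region mask as a BED file
#'
#' @param mask a \code{\link{region_mask}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(mask, path) {
  utils::write.table(
    data.frame(mask$chrom, format(mask$start, scientific = FALSE,
                                  trim = TRUE),
               format(mask$end, scientific = FALSE, trim = TRUE)),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}
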