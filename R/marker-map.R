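#' Construct a marker map
#'
#' Genetic map: per marker chromosome, identifier, genetic position (cM) and
#' physical position (1-based bp). Within a chromosome, cM must be
#' non-decreasing with bp.
#'
#' @param chrom,id,cM,bp per-marker vectors.
#' @return An object of class \code{"marker_map"} (a data.frame).
#' @export
marker_map <- function(chrom, id, cM, bp) {
  m <- data.frame(chrom = as.character(chrom), id = as.character(id),
                  cM = as.numeric(cM), bp = as.integer(bp),
                  stringsAsFactors = FALSE)
  m <- m[.variant_order(m$chrom, m$bp), ]
  rownames(m) <- NULL
  for (ch in unique(m$chrom)) {
    cm <- m$cM[m$chrom == ch]
    .stop_if(any(diff(cm) < 0),
             "cM must be non-decreasing with bp on chromosome '", ch, "'")
  }
  .check_positions(m$chrom, m$bp)
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Read a 4-column genetic map file
#'
#' Whitespace-separated columns: chromosome, marker id, cM, bp.
#'
#' @param map_source path to the map file.
#' @return A \code{\link{marker_map}}.
#' @export
read_marker_map <- function(map_source) {
  x <- utils::read.table(map_source, header = FALSE,
                         col.names = c("chrom", "id", "cM", "bp"),
                         colClasses = c("character", "character",
                                        "numeric", "integer"))
  marker_map(x$chrom, x$id, x$cM, x$bp)
}

#' Write a marker map file
#'
#' @param map a \code{\link{marker_map}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map[, c("chrom", "id", "cM", "bp")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}

# linear interpolation cM -> bp on one chromosome, anchored at the terminal
# markers (positions outside the marker span clamp to the ends)
cm_to_bp <- function(map, chrom, cm) {
  m <- map[map$chrom == chrom, ]
  .stop_if(nrow(m) == 0, "no markers on chromosome '", chrom, "'")
  if (nrow(m) == 1) return(rep(m$bp, length(cm)))
  stats::approx(m$cM, m$bp, xout = cm, ties = "ordered", rule = 2)$y
}

# map length in cM per chromosome
map_cm_length <- function(map) {
  vapply(split(map$cM, map$chrom), function(x) max(x) - min(x), 0)
}
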