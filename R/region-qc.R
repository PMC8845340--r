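# Region-level exclusion: chromosome ends, high-coverage windows, and
# recombination-peak flagging with inheritance-vector correlation.

#' Per-interval recombination rates from crossover calls
#'
#' Each crossover whose localization interval spans m adjacent-marker
#' intervals contributes 1/m to each of them (unbiased under uniform
#' localization uncertainty); the rate is the total divided by the number of
#' meioses.
#'
#' @param calls data.frame(chrom, start, end) of crossover calls.
#' @param positions named list (per chromosome) of sorted marker bp
#'   positions, or a numeric vector for a single chromosome.
#' @param n_meioses number of informative meioses.
#' @return data.frame(chrom, start, end, rate): one row per adjacent-marker
#'   interval (start/end are the flanking marker positions).
#' @export
interval_recombination_rates <- function(calls, positions, n_meioses) {
  .stop_if(n_meioses <= 0, "n_meioses must be > 0")
  if (!is.list(positions)) {
    positions <- stats::setNames(list(positions),
                                 unique(c(calls$chrom, "chr1"))[1])
  }
  out <- list()
  for (ch in names(positions)) {
    p <- positions[[ch]]
    if (length(p) < 2) next
    w <- rep(0, length(p) - 1)
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    if (nrow(cc) > 0) {
      li <- findInterval(cc$start, p)
      ri <- findInterval(cc$end - 1e-9, p)  # interval left of the end marker
      for (i in seq_len(nrow(cc))) {
        span <- seq.int(max(li[i], 1L), max(ri[i], li[i], 1L))
        w[span] <- w[span] + 1 / length(span)
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = p[-length(p)], end = p[-1],
                            rate = w / n_meioses, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag putative map-error regions from segregation patterns
#'
#' Candidate regions are marker runs bounded on both sides by
#' adjacent-marker intervals with recombination rate above
#' \code{rate_threshold} and spanning at most \code{max_span_bp}. For each
#' candidate, every meiosis's majority parental origin inside the region is
#' correlated (across meioses, 0/1 coding) with its majority origin in
#' flanking windows of \code{flank_markers} informative markers per side; a
#' squared correlation below \code{r2_threshold} means the region segregates
#' independently of its neighbourhood -- a marker-placement artifact, not a
#' recombination hotspot -- and it is masked. Chromosome extremities whose
#' terminal interval exceeds the rate threshold are masked as well. Rates
#' are recomputed after each masking pass until no new region is flagged.
#'
#' @param origins per-meiosis origin vectors as returned in
#'   \code{detect_crossovers()$origins}.
#' @param r2_threshold squared-correlation threshold (default 0.90).
#' @param rate_threshold recombination-rate threshold (default 0.05).
#' @param max_span_bp maximal candidate span (default 1 Mb).
#' @param flank_markers informative markers per flank (default 50).
#' @param min_meioses minimal informative meioses to assess a candidate
#'   (skipped with a warning below this).
#' @param min_support passed to \code{\link{call_crossovers}}.
#' @param max_iter safety bound on masking passes.
#' @return A \code{\link{region_mask}} with attribute \code{"flags"}: a
#'   data.frame describing each flagged region (chrom, start, end, reason,
#'   r2).
#' @export
flag_map_error_regions <- function(origins, r2_threshold = 0.90,
                                   rate_threshold = 0.05,
                                   max_span_bp = 1e6, flank_markers = 50L,
                                   min_meioses = 20L, min_support = 3L,
                                   max_iter = 10L) {
  mask <- region_mask()
  flags <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), reason = character(), r2 = numeric(),
                      stringsAsFactors = FALSE)
  chroms <- unique(unlist(lapply(origins, names)))
  for (iter in seq_len(max_iter)) {
    new_flag <- FALSE
    for (ch in chroms) {
      # current (unmasked) view of every meiosis on this chromosome
      mei <- lapply(origins, function(m) {
        v <- m[[ch]]
        if (is.null(v)) return(NULL)
        keep <- !mask_covers(mask, rep(ch, length(v$positions)),
                             v$positions)
        list(positions = v$positions[keep], origin = v$origin[keep])
      })
      mei <- Filter(function(v) !is.null(v) && length(v$positions) > 0, mei)
      if (length(mei) == 0) next
      grid <- sort(unique(unlist(lapply(mei, `[[`, "positions"))))
      if (length(grid) < 3) next
      calls <- do.call(rbind, lapply(mei, function(v) {
        cc <- call_crossovers(v$origin, v$positions, min_support)
        if (nrow(cc) == 0) return(NULL)
        data.frame(chrom = ch, start = cc$start, end = cc$end,
                   stringsAsFactors = FALSE)
      }))
      if (is.null(calls)) calls <- data.frame(chrom = character(),
                                              start = numeric(),
                                              end = numeric())
      track <- interval_recombination_rates(
        calls, stats::setNames(list(grid), ch), length(mei))
      hot <- which(track$rate > rate_threshold)
      if (length(hot) == 0) next

      # terminal intervals: inflated recombination at chromosome extremity
      for (side in c("first", "last")) {
        j <- if (side == "first") 1L else nrow(track)
        if (j %in% hot) {
          iv <- if (side == "first") c(grid[1] - 1, grid[1]) else
            c(grid[length(grid)] - 1, grid[length(grid)])
          if (!any(mask_covers(mask, ch, iv[2]))) {
            mask <- mask_union(mask, region_mask(ch, iv[1], iv[2]))
            flags <- rbind(flags, data.frame(
              chrom = ch, start = iv[1], end = iv[2],
              reason = "terminal_inflated_rate", r2 = NA_real_,
              stringsAsFactors = FALSE))
            new_flag <- TRUE
          }
        }
      }
      internal <- setdiff(hot, c())
      if (length(internal) >= 2) {
        pairs <- cbind(internal[-length(internal)], internal[-1])
        for (k in seq_len(nrow(pairs))) {
          j1 <- pairs[k, 1]; j2 <- pairs[k, 2]
          # markers strictly between the two hot intervals: grid[j1+1..j2]
          region <- c(grid[j1 + 1], grid[j2])
          if (region[2] - region[1] > max_span_bp) next
          r2 <- .region_flank_r2(mei, region, flank_markers)
          if (r2$n < min_meioses) {
            warning("candidate region ", ch, ":", region[1], "-",
                    region[2], " skipped (", r2$n,
                    " informative meioses)")
            next
          }
          if (is.na(r2$r2)) next
          if (r2$r2 < r2_threshold) {
            mask <- mask_union(mask,
                               region_mask(ch, region[1] - 1, region[2]))
            flags <- rbind(flags, data.frame(
              chrom = ch, start = region[1] - 1, end = region[2],
              reason = "low_flank_r2", r2 = r2$r2,
              stringsAsFactors = FALSE))
            new_flag <- TRUE
          }
        }
      }
    }
    if (!new_flag) break
  }
  attr(mask, "flags") <- flags
  mask
}

# majority origin inside [region] vs in flanking windows, correlated across
# meioses
.region_flank_r2 <- function(mei, region, flank_markers) {
  inside <- flank <- rep(NA_real_, length(mei))
  for (i in seq_along(mei)) {
    v <- mei[[i]]
    in_r <- v$positions >= region[1] & v$positions <= region[2]
    if (!any(in_r)) next
    left <- which(v$positions < region[1])
    right <- which(v$positions > region[2])
    fl <- c(utils::tail(left, flank_markers),
            utils::head(right, flank_markers))
    if (length(fl) == 0) next
    inside[i] <- round(mean(v$origin[in_r] == 2L))
    flank[i] <- round(mean(v$origin[fl] == 2L))
  }
  ok <- !is.na(inside) & !is.na(flank)
  n <- sum(ok)
  if (n < 3 || stats::sd(inside[ok]) == 0 || stats::sd(flank[ok]) == 0) {
    return(list(r2 = NA_real_, n = n))
  }
  list(r2 = stats::cor(inside[ok], flank[ok])^2, n = n)
}

#' Flag high-coverage windows per individual
#'
#' Windows whose depth exceeds \code{factor} times the individual's average
#' depth are flagged; the union over individuals is returned.
#'
#' @param depth_track data.frame(chrom, start, end, sample, depth) with
#'   0-based half-open windows.
#' @param factor multiple of the individual mean (default 6).
#' @return A \code{\link{region_mask}}.
#' @export
flag_high_coverage_regions <- function(depth_track, factor = 6) {
  .stop_if(is.null(depth_track) || nrow(depth_track) == 0,
           "empty depth track")
  means <- tapply(depth_track$depth, depth_track$sample, mean)
  hi <- depth_track$depth > factor * means[depth_track$sample]
  region_mask(depth_track$chrom[hi], depth_track$start[hi],
              depth_track$end[hi])
}

#' Build the combined exclusion mask
#'
#' Union of the first and last \code{end_trim_bp} of every chromosome with
#' any number of additional masks.
#'
#' @param chrom_lengths named vector of chromosome bp lengths.
#' @param ... additional \code{\link{region_mask}} objects.
#' @param end_trim_bp bp trimmed from each chromosome end (default 10 kb).
#' @return A merged \code{\link{region_mask}}.
#' @export
build_exclusion_mask <- function(chrom_lengths, ..., end_trim_bp = 1e4) {
  .stop_if(end_trim_bp < 0, "end_trim_bp must be >= 0")
  ends <- region_mask()
  if (end_trim_bp > 0) {
    ch <- names(chrom_lengths)
    whole <- 2 * end_trim_bp >= chrom_lengths
    if (any(whole)) {
      warning("end trim covers whole chromosome(s): ",
              paste(ch[whole], collapse = ", "))
    }
    ends <- region_mask(
      rep(ch, 2),
      c(rep(0, length(ch)), pmax(chrom_lengths - end_trim_bp, 0)),
      c(pmin(end_trim_bp, chrom_lengths), chrom_lengths))
  }
  mask_union(ends, ...)
}
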