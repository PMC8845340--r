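#' Corrupt phased haplotypes with controlled switch errors
#'
#' Emulates the error modes of population-based phasing output against a
#' known truth: long switches (haplotype labels swap downstream of each
#' breakpoint, cumulatively, drawn as a homogeneous Poisson process along the
#' chromosome), point switches (independent per-site label flips), and loss
#' of phase at a random fraction of heterozygous sites. Genotypes are never
#' altered.
#'
#' @param truth a fully phased \code{\link{haplotype_set}}.
#' @param long_switch_rate_per_Mb Poisson rate of long-switch breakpoints per
#'   Mb per individual-chromosome.
#' @param point_switch_rate_per_site per-site label-flip probability.
#' @param unphase_fraction fraction of heterozygous sites set to unphased.
#' @param seed integer seed.
#' @param chrom_lengths optional named bp lengths (defaults to the largest
#'   marker position per chromosome).
#' @return list(haplotypes = corrupted \code{\link{haplotype_set}},
#'   corruption_log = data.frame(sample, chrom, type, pos)) where type is
#'   "long_switch", "point_switch" or "unphase".
#' @export
corrupt_haplotypes <- function(truth, long_switch_rate_per_Mb = 0,
                               point_switch_rate_per_site = 0,
                               unphase_fraction = 0, seed = 1L,
                               chrom_lengths = NULL) {
  .stop_if(long_switch_rate_per_Mb < 0 || point_switch_rate_per_site < 0 ||
             unphase_fraction < 0 || unphase_fraction > 1,
           "rates must be non-negative (unphase_fraction in [0, 1])")
  .with_seed(seed, {
    hapA <- truth$hapA; hapB <- truth$hapB; phased <- truth$phased
    chroms <- unique(truth$chrom)
    if (is.null(chrom_lengths)) {
      chrom_lengths <- vapply(chroms, function(ch)
        max(truth$pos[truth$chrom == ch]), 0)
    }
    log_rows <- list()
    add_log <- function(sample, chrom, type, pos) {
      if (length(pos) == 0) return()
      log_rows[[length(log_rows) + 1]] <<-
        data.frame(sample = sample, chrom = chrom, type = type, pos = pos,
                   stringsAsFactors = FALSE)
    }
    for (s in seq_along(truth$sample_ids)) {
      sid <- truth$sample_ids[s]
      for (ch in chroms) {
        idx <- which(truth$chrom == ch)
        pos <- truth$pos[idx]
        flip <- rep(FALSE, length(idx))
        if (long_switch_rate_per_Mb > 0) {
          L <- chrom_lengths[[ch]]
          n_bk <- stats::rpois(1, long_switch_rate_per_Mb * L / 1e6)
          if (n_bk > 0) {
            bk <- sort(stats::runif(n_bk, 0, L))
            flip <- (findInterval(pos, bk) %% 2L) == 1L
            add_log(sid, ch, "long_switch", bk)
          }
        }
        if (point_switch_rate_per_site > 0) {
          pt <- stats::runif(length(idx)) < point_switch_rate_per_site
          flip <- xor(flip, pt)
          add_log(sid, ch, "point_switch", pos[pt])
        }
        if (any(flip)) {
          i <- idx[flip]
          tmp <- hapA[i, s]
          hapA[i, s] <- hapB[i, s]
          hapB[i, s] <- tmp
        }
        if (unphase_fraction > 0) {
          het <- which(hapA[idx, s] + hapB[idx, s] == 1L & phased[idx, s])
          n_un <- round(unphase_fraction * length(het))
          if (n_un > 0) {
            un <- sort(sample(het, n_un))
            phased[idx[un], s] <- FALSE
            add_log(sid, ch, "unphase", pos[un])
          }
        }
      }
    }
    log <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
      data.frame(sample = character(), chrom = character(),
                 type = character(), pos = numeric(),
                 stringsAsFactors = FALSE)
    list(haplotypes = haplotype_set(truth$chrom, truth$pos,
                                    truth$sample_ids, hapA, hapB, phased),
         corruption_log = log)
  })
}

#' Inject artifact variants that violate Mendelian transmission
#'
#' Appends variants whose genotypes ignore the pedigree, emulating
#' library/alignment artifacts that segregate like noise rather than like
#' true SNPs. Modes: \code{"iid_hwe"} draws each individual's genotype
#' independently from Hardy-Weinberg proportions; \code{"excess_het"} makes
#' every carrier heterozygous. Artifacts exist only in the observed genotype
#' matrix and are flagged in the \code{artifact} vector so that QC
#' recall/precision is computable.
#'
#' @param sim a \code{"sim_truth"} object.
#' @param n_artifacts number of artifact variants to add.
#' @param mode "iid_hwe" or "excess_het".
#' @param freq alternate-allele frequency of the artifacts.
#' @param seed integer seed.
#' @return The modified \code{"sim_truth"}.
#' @export
inject_artifact_variants <- function(sim, n_artifacts, mode = "iid_hwe",
                                     freq = 0.3, seed = 1L) {
  .stop_if(n_artifacts < 0, "n_artifacts must be >= 0")
  mode <- match.arg(mode, c("iid_hwe", "excess_het"))
  if (n_artifacts == 0) return(sim)
  .with_seed(seed, {
    obs <- sim$observed
    n_samp <- length(obs$sample_ids)
    chroms <- unique(obs$chrom)
    ch <- sample(chroms, n_artifacts, replace = TRUE)
    pos <- integer(n_artifacts)
    for (i in seq_len(n_artifacts)) {
      used <- c(obs$pos[obs$chrom == ch[i]], pos[ch == ch[i] & seq_len(n_artifacts) < i])
      repeat {
        p <- sample.int(max(obs$pos[obs$chrom == ch[i]]), 1)
        if (!(p %in% used)) break
      }
      pos[i] <- p
    }
    g <- matrix(stats::rbinom(n_artifacts * n_samp, 2L, freq),
                nrow = n_artifacts)
    if (mode == "excess_het") g <- pmin(g, 1L)
    chrom_all <- c(obs$chrom, ch)
    pos_all <- c(obs$pos, pos)
    calls_all <- rbind(obs$calls, g)
    art_all <- c(sim$artifact, rep(TRUE, n_artifacts))
    o <- .variant_order(chrom_all, pos_all)
    sim$observed <- genotype_matrix(chrom_all[o], pos_all[o],
                                    obs$sample_ids,
                                    calls_all[o, , drop = FALSE])
    sim$artifact <- art_all[o]
    sim
  })
}

#' Relocate a marker block to emulate a genome-assembly map error
#'
#' Picks (or accepts) a contiguous block of markers spanning about
#' \code{block_span_bp} and shifts its stored positions by
#' \code{destination_offset_bp}; genotype data are untouched, only
#' coordinates move, so the block keeps segregating according to its true
#' location. The relocation is recorded in \code{map_error_log}.
#'
#' @param sim a \code{"sim_truth"} object.
#' @param block_span_bp approximate bp span of the relocated block.
#' @param destination_offset_bp signed bp offset applied to the block.
#' @param chrom chromosome to corrupt (default: first).
#' @param block_start_bp optional left edge of the block (random if NULL).
#' @param seed integer seed.
#' @param max_retries redraw attempts when the moved block would collide
#'   with existing marker positions or leave the chromosome.
#' @return The modified \code{"sim_truth"} (observed, truth and map
#'   coordinates all updated and re-sorted).
#' @export
inject_map_errors <- function(sim, block_span_bp, destination_offset_bp,
                              chrom = NULL, block_start_bp = NULL,
                              seed = 1L, max_retries = 100L) {
  if (destination_offset_bp == 0) return(sim)
  .with_seed(seed, {
    obs <- sim$observed
    chrom <- chrom %||% unique(obs$chrom)[1]
    on_ch <- which(obs$chrom == chrom)
    pos <- obs$pos[on_ch]
    L <- max(pos)
    # coordinate splice: the block is cut out of its true location (the
    # hole closes, downstream coordinates shift back) and inserted as a
    # contiguous foreign segment at the destination gap (downstream
    # coordinates shift forward); marker spacing inside the block and
    # everywhere else is preserved
    pick <- function(start) {
      in_block <- pos >= start & pos < start + block_span_bp
      n_blk <- sum(in_block)
      if (n_blk == 0) return(NULL)
      nat <- !in_block
      gap_t <- round(stats::median(diff(pos)))
      b0 <- min(pos[in_block]); b1 <- max(pos[in_block])
      if (!any(nat & pos < b0) || !any(nat & pos > b1)) return(NULL)
      lo <- max(pos[nat & pos < b0]); hi <- min(pos[nat & pos > b1])
      shift_rem <- (hi - lo) - gap_t
      npos <- pos
      npos[nat & pos > b1] <- pos[nat & pos > b1] - shift_rem
      dest <- b0 + destination_offset_bp
      if (dest > b1) dest <- dest - shift_rem
      nat_pos <- npos[nat]
      if (dest <= min(nat_pos) || dest > max(nat_pos)) return(NULL)
      g0 <- max(nat_pos[nat_pos <= dest])
      g1 <- min(nat_pos[nat_pos > dest])
      shift_ins <- (b1 - b0) + 2 * gap_t - (g1 - g0)
      if (shift_ins > 0) {
        npos[nat & npos >= g1] <- npos[nat & npos >= g1] + shift_ins
      }
      new_blk <- g0 + gap_t + (pos[in_block] - b0)
      npos[in_block] <- new_blk
      if (any(diff(sort(npos)) <= 0) || min(npos) < 1) return(NULL)
      list(in_block = in_block, new_pos = as.integer(new_blk),
           all_pos = as.integer(npos))
    }
    res <- NULL
    if (!is.null(block_start_bp)) {
      res <- pick(block_start_bp)
      .stop_if(is.null(res), "requested block cannot be relocated ",
               "(empty, out of bounds, or collides with existing markers)")
    } else {
      for (r in seq_len(max_retries)) {
        res <- pick(stats::runif(1, 1, L - block_span_bp))
        if (!is.null(res)) break
      }
      .stop_if(is.null(res), "no relocatable block found after ",
               max_retries, " attempts")
    }
    moved <- on_ch[res$in_block]
    log_row <- data.frame(
      chrom = chrom,
      orig_start = min(obs$pos[moved]), orig_end = max(obs$pos[moved]),
      new_start = min(res$new_pos), new_end = max(res$new_pos),
      n_markers = length(moved), stringsAsFactors = FALSE)

    new_all <- obs$pos
    new_all[on_ch] <- res$all_pos
    o <- .variant_order(obs$chrom, new_all)
    sim$observed <- genotype_matrix(obs$chrom[o], new_all[o],
                                    obs$sample_ids,
                                    obs$calls[o, , drop = FALSE])
    sim$artifact <- sim$artifact[o]
    # keep the truth axis aligned when truth covers the same variants
    if (length(sim$truth$pos) == length(obs$pos) &&
        all(sim$truth$pos == obs$pos & sim$truth$chrom == obs$chrom)) {
      tr <- sim$truth
      sim$truth <- haplotype_set(tr$chrom[o], new_all[o], tr$sample_ids,
                                 tr$hapA[o, , drop = FALSE],
                                 tr$hapB[o, , drop = FALSE],
                                 tr$phased[o, , drop = FALSE])
      m <- sim$map
      m$bp[match(paste(obs$chrom, obs$pos), paste(m$chrom, m$bp))] <- new_all
      m <- m[.variant_order(m$chrom, m$bp), ]
      # the stored cM scale now disagrees with bp order by design; rebuild a
      # naive linear map on the shuffled coordinates, as a user of corrupted
      # coordinates would
      for (chx in unique(m$chrom)) {
        i <- m$chrom == chx
        rng <- range(m$bp[i])
        cm_rng <- range(sim$map$cM[sim$map$chrom == chx])
        m$cM[i] <- cm_rng[1] + (m$bp[i] - rng[1]) / diff(rng) * diff(cm_rng)
      }
      sim$map <- marker_map(m$chrom, m$id, m$cM, m$bp)
    }
    sim$map_error_log <- rbind(sim$map_error_log, log_row)
    sim
  })
}
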