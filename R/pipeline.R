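# End-to-end driver: simulate -> trio-phase -> variant QC -> region QC ->
# crossover diagnostic -> corrupt (stand-in for an external phaser) ->
# evaluate; consolidated TSV + JSON reports.

#' Run the full evaluation pipeline on simulated data
#'
#' Executes every stage against a seeded synthetic data set: genotype
#' simulation; genetic-rule variant QC; region QC (chromosome ends plus
#' high-coverage windows from a simulated depth track); gold-standard
#' construction by Mendelian trio/duo phasing; the crossover-count
#' diagnostic; corruption of the true haplotypes as a stand-in for an
#' external phaser's output; and metric evaluation of the corrupted
#' haplotypes against the gold standard.
#'
#' @param config list (or path to a JSON file) with optional elements:
#'   \code{sim} (arguments to \code{\link{sim_config}}), \code{scenario}
#'   ("validation_only" = trio offspring enter evaluation, the default, or
#'   "full_cohort" = all offspring with a genotyped parent),
#'   \code{corruption} (arguments to \code{\link{corrupt_haplotypes}}),
#'   \code{qc_thresholds} (see \code{\link{apply_variant_filters}}),
#'   \code{end_trim_bp}, \code{min_support}, \code{seed}.
#' @param out_dir output directory for TSV/JSON artifacts (created);
#'   \code{NULL} writes nothing.
#' @return list(sim, qc, gold, co, eval, report, files) invisibly; the
#'   \code{report} element is the consolidated summary list.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  scenario <- match.arg(config$scenario %||% "validation_only",
                        c("validation_only", "full_cohort"))
  seed <- as.integer(config$seed %||% 1L)
  sim_args <- config$sim %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)

  sim <- simulate_dataset(cfg)
  qc <- apply_variant_filters(sim$observed, sim$pedigree,
                              thresholds = config$qc_thresholds %||% list())
  chrom_lengths <- stats::setNames(cfg$chrom_bp_lengths,
                                   paste0("chr", seq_len(cfg$n_chrom)))
  depth <- simulate_depth_track(chrom_lengths, window_bp = 1e5,
                                sample_ids = sim$observed$sample_ids[1:5],
                                seed = seed + 1L)
  mask <- build_exclusion_mask(chrom_lengths,
                               flag_high_coverage_regions(depth),
                               end_trim_bp = config$end_trim_bp %||% 1e4)
  gm <- apply_region_mask(qc$genotypes, mask)

  gold <- phase_pedigree(gm, sim$pedigree)
  # the site-wise gold standard leaves founders unphased, so the crossover
  # diagnostic takes its parent haplotypes from the simulation truth (on
  # real data: any phased parent VCF)
  truth_on_panel <- .subset_truth_to(sim$truth, gm)
  co <- detect_crossovers(truth_on_panel, gm, sim$pedigree,
                          min_support = config$min_support %||% 3L)
  expected_co <- sum(cfg$chrom_cM_lengths) / 100
  co_sum <- co_summary(co$calls, co$meioses,
                       expected_per_meiosis = expected_co)

  # stand-in for an external population-based phaser
  corr_args <- utils::modifyList(list(long_switch_rate_per_Mb = 0.02,
                                      point_switch_rate_per_site = 1e-4,
                                      unphase_fraction = 0,
                                      seed = seed + 2L),
                                 config$corruption %||% list())
  corr <- do.call(corrupt_haplotypes, c(list(truth = truth_on_panel),
                                        corr_args))

  trios <- find_trios(sim$pedigree, gm$sample_ids)
  duos <- find_duos(sim$pedigree, gm$sample_ids)
  inds <- if (scenario == "validation_only") trios$offspring else
    c(trios$offspring, duos$offspring)
  dists <- config$distances_bp %||% (c(0.01, 0.1, 1, 2, 5, 10, 50) * 1e6)
  dists <- dists[dists < max(cfg$chrom_bp_lengths)]
  ev <- evaluate_phasing(gold$haplotypes, corr$haplotypes,
                         individuals = inds, distances_bp = dists,
                         seed = seed + 3L)

  report <- make_report(ev, co_sum, qc)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      f <- file.path(out_dir, name)
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    }
    files <- c(
      wr(ev$per_individual, "per_individual.tsv"),
      wr(ev$cohort, "cohort_summary.tsv"),
      wr(ev$pairwise, "pairwise_accuracy.tsv"),
      wr(ev$genome_fraction, "genome_fraction.tsv"),
      wr(co_sum$per_meiosis, "co_per_meiosis.tsv"),
      wr(qc$report, "variant_qc_report.tsv"))
    json_f <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, json_f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, json_f)
    bed_f <- file.path(out_dir, "exclusion_mask.bed")
    write_bed(mask, bed_f)
    files <- c(files, bed_f)
  }
  invisible(list(sim = sim, qc = qc, mask = mask, gold = gold, co = co,
                 co_summary = co_sum, eval = ev, report = report,
                 files = files))
}

# restrict the simulation truth to the variants of a filtered panel
.subset_truth_to <- function(truth, gm) {
  key_t <- paste(truth$chrom, truth$pos)
  key_g <- paste(gm$chrom, gm$pos)
  subset_hap_variants(truth, key_t %in% key_g)
}

#' Consolidated machine-readable report
#'
#' Cohort min/mean/median/max per metric, the genome-fraction and pairwise
#' tables, crossover diagnostics and variant-QC attrition, as one list that
#' serializes directly to JSON.
#'
#' @param eval a \code{"phasing_eval"}.
#' @param co_sum a \code{"co_summary"} (optional).
#' @param qc a \code{"variant_qc"} (optional).
#' @return A named list.
#' @export
make_report <- function(eval, co_sum = NULL, qc = NULL) {
  r <- list(
    n_individuals = nrow(eval$per_individual),
    cohort = eval$cohort,
    genome_fraction = eval$genome_fraction,
    pairwise_accuracy = eval$pairwise)
  if (!is.null(co_sum)) {
    r$crossovers <- list(mean_overall = co_sum$mean_overall,
                         mean_by_sex = as.list(co_sum$mean_by_sex),
                         expected = co_sum$expected,
                         inflation = co_sum$inflation)
  }
  if (!is.null(qc)) {
    r$variant_qc <- list(attrition = as.list(qc$attrition),
                         chance_model = qc$chance_model)
  }
  r
}
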