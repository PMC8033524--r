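#' Run the full synthetic screen end to end
#'
#' Generates a reference and truth table, simulates splinkerette libraries,
#' trims the transposon prefix, aligns pairs with the uniqueness contract,
#' calls TTAA-filtered integration sites with shear-end diversity,
#' annotates them against the gene hierarchy, builds the per-sample
#' percentage matrix and ranks genes enriched in the metastatic group.
#'
#' @param config A [sim_config()].
#' @param denominator Passed to [percentage_matrix()].
#' @return list with `ref`, `truth`, `trim_stats`, `align_stats`, `sites`
#'   (kept, all samples), `rejected`, `annotated`, `matrix`, `ranking`,
#'   `recovery` (see [evaluate_recovery()]).
#' @export
run_screen <- function(config, denominator = "diversity") {
  ref <- gen_reference(config)
  truth <- plant_insertions(ref, config)
  sim <- simulate_reads(ref, truth, config)

  all_sites <- list()
  all_rejected <- list()
  trim_stats <- list()
  align_stats <- list()
  for (sid in names(sim$reads)) {
    tr <- trim_prefix(sim$reads[[sid]])
    trim_stats[[sid]] <- tr$stats
    al <- align_pairs(tr$pairs, ref$genome)
    align_stats[[sid]] <- al$stats
    sites <- call_sites(al$pairs, ref$genome, sid)
    flt <- filter_ttaa(sites)
    all_sites[[sid]] <- flt$kept
    all_rejected[[sid]] <- flt$rejected
  }
  sites <- do.call(rbind, all_sites)
  rownames(sites) <- NULL
  rejected <- do.call(rbind, all_rejected)

  annotated <- classify_sites(sites, ref$transcripts)
  mat <- percentage_matrix(annotated, denominator = denominator)
  ranking <- rank_enriched(mat, sim_samples(config))

  list(ref = ref, truth = truth, trim_stats = trim_stats,
       align_stats = align_stats, sites = sites, rejected = rejected,
       annotated = annotated, matrix = mat, ranking = ranking,
       recovery = evaluate_recovery(sites, truth))
}

#' Compare called sites against a planted truth table
#'
#' @param sites Kept site table (all samples).
#' @param truth Truth table from [plant_insertions()].
#' @return list: `n_truth`, `n_called`, `n_recovered` (exact sample +
#'   chromosome + strand + coordinate matches), `recovery` (fraction of
#'   planted sites recovered), `spurious` (called sites not in the truth),
#'   `spurious_high_diversity` (spurious sites with diversity >= 2),
#'   `total_fragments` (sum of called diversity, the denominator for
#'   spurious-rate tolerances).
#' @export
evaluate_recovery <- function(sites, truth) {
  key <- function(d) paste(d$sample_id, d$chrom, d$strand, d$coord)
  tk <- key(truth)
  sk <- key(sites)
  recovered <- tk %in% sk
  spurious <- !(sk %in% tk)
  list(
    n_truth = nrow(truth),
    n_called = nrow(sites),
    n_recovered = sum(recovered),
    recovery = mean(recovered),
    spurious = sum(spurious),
    spurious_high_diversity = sum(spurious & sites$diversity >= 2L),
    total_fragments = sum(sites$diversity)
  )
}

#' Enrichment ranking straight from a truth table
#'
#' Skips the read level: treats planted insertions as called sites (which
#' the no-noise read pipeline reproduces exactly), annotates, normalizes
#' and ranks. Used for seed-replicated power and type-I calibration of the
#' enrichment stage.
#'
#' @param config A [sim_config()].
#' @param ref Optional pre-built reference (so replicate seeds can share
#'   one genome).
#' @param denominator Passed to [percentage_matrix()].
#' @return list with `truth`, `annotated`, `matrix`, `ranking`.
#' @export
truth_ranking <- function(config, ref = NULL, denominator = "diversity") {
  if (is.null(ref)) ref <- gen_reference(config)
  truth <- plant_insertions(ref, config)
  pseudo <- data.frame(
    sample_id = truth$sample_id, chrom = truth$chrom, strand = truth$strand,
    coord = truth$coord, diversity = truth$true_diversity,
    stringsAsFactors = FALSE)
  annotated <- classify_sites(pseudo, ref$transcripts)
  mat <- percentage_matrix(annotated, denominator = denominator)
  ranking <- rank_enriched(mat, sim_samples(config))
  list(truth = truth, annotated = annotated, matrix = mat, ranking = ranking)
}
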