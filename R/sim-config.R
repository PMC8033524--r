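#' Configuration for the synthetic splinkerette screen generator
#'
#' Bundles every tunable of the synthetic-data module: genome geometry, gene
#' content, library chemistry (fragment size, PCR duplication, sequencing
#' error, contaminant fraction, barcodes) and the screen design (sample
#' groups and genes with elevated insertion load in one group).
#'
#' Defaults emulate the screen this pipeline targets: sonication fragments
#' around 250 bp, 8-nt sample barcodes, roughly 1% of read pairs lacking the
#' transposon-derived prefix, and a tumour-versus-metastatic two-group
#' design.
#'
#' @param seed Integer seed; all generator stages derive their streams
#'   from it, so an identical config reproduces identical output.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total genes, distributed round-robin over chromosomes.
#' @param noncoding_frac Fraction of genes without an annotated CDS.
#' @param n_insertions Background insertions planted per sample.
#' @param diversity_lambda Per-site shear-end diversity is `1 + Poisson(lambda)`.
#' @param fragment_length_mean,fragment_length_sd Sonication fragment length
#'   distribution (bp), truncated below at `max(20, read_length/2)`.
#' @param read_length Read length (nt) of both mates.
#' @param pcr_dup_mean Each unique fragment is sequenced `1 + Poisson(mean)`
#'   times.
#' @param seq_error_rate Per-base substitution error probability.
#' @param contaminant_frac Fraction of pairs whose read 1 does not carry the
#'   transposon prefix (non-transposon material).
#' @param barcode_length Sample barcode length (nt).
#' @param inline_barcodes If `TRUE` the barcode is prepended to read 2
#'   (splinkerette-primer side); by default barcodes live in read headers.
#' @param groups Named integer vector: samples per group,
#'   e.g. `c(tumour = 16, metastatic = 18)`.
#' @param enriched_genes `NULL` or a data.frame with columns `gene_id`,
#'   `group`, `fold`: samples of `group` receive `fold`-elevated expected
#'   insertion diversity within that gene's span (promoter through gene end).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e6,
                       n_genes = 50L,
                       noncoding_frac = 0.2,
                       n_insertions = 100L,
                       diversity_lambda = 2,
                       fragment_length_mean = 250,
                       fragment_length_sd = 60,
                       read_length = 100L,
                       pcr_dup_mean = 5,
                       seq_error_rate = 0.001,
                       contaminant_frac = 0.01,
                       barcode_length = 8L,
                       inline_barcodes = FALSE,
                       groups = c(tumour = 4L, metastatic = 4L),
                       enriched_genes = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    noncoding_frac = noncoding_frac,
    n_insertions = as.integer(n_insertions),
    diversity_lambda = diversity_lambda,
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    read_length = as.integer(read_length),
    pcr_dup_mean = pcr_dup_mean,
    seq_error_rate = seq_error_rate,
    contaminant_frac = contaminant_frac,
    barcode_length = as.integer(barcode_length),
    inline_barcodes = isTRUE(inline_barcodes),
    groups = groups,
    enriched_genes = enriched_genes
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(noncoding_frac = cfg$noncoding_frac,
             seq_error_rate = cfg$seq_error_rate,
             contaminant_frac = cfg$contaminant_frac)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stopf("configuration error: %s must lie in [0, 1]",
          paste(names(rates)[bad], collapse = ", "))
  }
  if (cfg$fragment_length_mean < 20) {
    stopf("configuration error: fragment_length_mean must be >= 20 bp")
  }
  if (cfg$chrom_length < 10 * cfg$fragment_length_mean) {
    stopf("configuration error: chrom_length must be >= 10 x fragment_length_mean")
  }
  if (cfg$n_chroms < 1L || cfg$n_genes < 1L) {
    stopf("configuration error: need at least one chromosome and one gene")
  }
  if (is.null(names(cfg$groups)) || any(names(cfg$groups) == "") ||
      any(cfg$groups < 1L)) {
    stopf("configuration error: groups must be a named vector of positive counts")
  }
  # every chromosome must be able to host its share of genes
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  min_slot <- 6000  # smallest gene footprint incl. promoter clearance
  if (cfg$chrom_length - 2 * sim_edge_margin() < per_chrom * min_slot) {
    stopf("configuration error: chrom_length %d too small to host %d genes per chromosome",
          cfg$chrom_length, per_chrom)
  }
  if (!is.null(cfg$enriched_genes)) {
    need <- c("gene_id", "group", "fold")
    if (!all(need %in% names(cfg$enriched_genes))) {
      stopf("configuration error: enriched_genes needs columns %s",
            paste(need, collapse = ", "))
    }
    if (!all(cfg$enriched_genes$group %in% names(cfg$groups))) {
      stopf("configuration error: enriched_genes references unknown group(s)")
    }
    if (any(cfg$enriched_genes$fold < 0)) {
      stopf("configuration error: fold elevations must be >= 0")
    }
  }
  invisible(cfg)
}

# insertions are only planted this far from chromosome ends so that any
# sonication fragment (<= maxins) fits on the chromosome
sim_edge_margin <- function() 1100L

#' Sample sheet implied by a generator configuration
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `sample_id` and `group`.
#' @export
sim_samples <- function(config) {
  groups <- config$groups
  data.frame(
    sample_id = unlist(lapply(names(groups), function(g) {
      paste0(g, "_", seq_len(groups[[g]]))
    }), use.names = FALSE),
    group = rep(names(groups), times = as.integer(groups)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic screen configuration\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp, %d genes (%.0f%% non-coding)\n",
              x$n_chroms, format(x$chrom_length, big.mark = ","),
              x$n_genes, 100 * x$noncoding_frac))
  cat(sprintf("  library: fragments %g +/- %g bp, reads 2 x %d nt, PCR dup mean %g,\n",
              x$fragment_length_mean, x$fragment_length_sd,
              x$read_length, x$pcr_dup_mean))
  cat(sprintf("           error %g/base, contaminants %g, barcodes %d nt (%s)\n",
              x$seq_error_rate, x$contaminant_frac, x$barcode_length,
              if (x$inline_barcodes) "inline in read 2" else "in headers"))
  cat(sprintf("  design: %s; %d insertions/sample, diversity 1+Pois(%g)\n",
              paste(sprintf("%s n=%d", names(x$groups), x$groups), collapse = ", "),
              x$n_insertions, x$diversity_lambda))
  if (!is.null(x$enriched_genes) && nrow(x$enriched_genes)) {
    cat(sprintf("  enriched: %s\n",
                paste(sprintf("%s x%g in %s", x$enriched_genes$gene_id,
                              x$enriched_genes$fold, x$enriched_genes$group),
                      collapse = "; ")))
  }
  invisible(x)
}
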