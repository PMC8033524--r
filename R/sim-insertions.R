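#' TTAA tetranucleotide positions of a genome
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param margin Exclude positions closer than this to either chromosome end
#'   (0 keeps everything).
#' @return data.frame with columns `chrom`, `pos` (0-based start of the
#'   TTAA, so the motif occupies `[pos, pos + 4)`).
#' @export
ttaa_positions <- function(genome, margin = 0L) {
  out <- lapply(names(genome), function(ch) {
    m <- Biostrings::matchPattern("TTAA", genome[[ch]])
    pos <- BiocGenerics::start(m) - 1L
    len <- length(genome[[ch]])
    pos <- pos[pos >= margin & (pos + 4L) <= (len - margin)]
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# strand-aware gene span from promoter (2 kb upstream) through gene end
gene_spans <- function(transcripts, promoter = 2000L) {
  agg <- lapply(split(transcripts, transcripts$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1],
               start = min(g$tx_start), end = max(g$tx_end),
               stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, agg)
  sp$span_start <- ifelse(sp$strand == "+", sp$start - promoter, sp$start)
  sp$span_end <- ifelse(sp$strand == "+", sp$end, sp$end + promoter)
  sp$span_start <- pmax(sp$span_start, 0L)
  rownames(sp) <- NULL
  sp
}

#' Plant transposon insertions and draw a ground-truth table
#'
#' Background insertions are drawn uniformly over interior TTAA sites for
#' each sample; genes listed in `config$enriched_genes` additionally receive
#' extra insertions in the samples of the named group so that the expected
#' summed shear-end diversity within the gene's span (promoter through gene
#' end) is elevated `fold`-fold over background. Per-site diversity is
#' `1 + Poisson(diversity_lambda)`.
#'
#' An insertion on the `+` strand at TTAA position `p` has junction
#' coordinate `p + 4`; on the `-` strand the junction is `p`, so in both
#' cases the TTAA is the 4-mer immediately upstream of the first
#' transposon-adjacent base in read-1 orientation.
#'
#' @param ref Output of [gen_reference()].
#' @param config A [sim_config()].
#' @return data.frame (the truth table) with columns `sample_id`, `chrom`,
#'   `strand`, `coord` (0-based junction), `true_diversity`, `gene_id`
#'   (`NA` for sites outside every gene span).
#' @export
plant_insertions <- function(ref, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  tt <- ttaa_positions(ref$genome, margin = sim_edge_margin())
  if (is.null(tt) || nrow(tt) < config$n_insertions) {
    stopf("configuration error: fewer interior TTAA sites than insertions requested")
  }
  spans <- gene_spans(ref$transcripts)
  samples <- sim_samples(config)

  # TTAA content of each enriched gene's span (for expected-load arithmetic)
  enr <- config$enriched_genes
  enr_sites <- list()
  if (!is.null(enr) && nrow(enr)) {
    for (i in seq_len(nrow(enr))) {
      sp <- spans[spans$gene_id == enr$gene_id[i], ]
      if (nrow(sp) == 0L) {
        stopf("configuration error: enriched gene %s not in the reference", enr$gene_id[i])
      }
      in_span <- tt$chrom == sp$chrom & tt$pos >= sp$span_start &
        (tt$pos + 4L) <= sp$span_end
      if (!any(in_span)) {
        warnf("enriched gene %s has no TTAA site in its span; skipped", enr$gene_id[i])
      }
      enr_sites[[i]] <- which(in_span)
    }
  }

  res <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    grp <- samples$group[s]
    idx <- sample.int(nrow(tt), config$n_insertions)
    strand <- sample(c("+", "-"), config$n_insertions, replace = TRUE)
    rows <- data.frame(
      sample_id = sid, chrom = tt$chrom[idx], strand = strand,
      pos = tt$pos[idx], stringsAsFactors = FALSE
    )
    if (!is.null(enr) && nrow(enr)) {
      for (i in seq_len(nrow(enr))) {
        if (enr$group[i] != grp || length(enr_sites[[i]]) == 0L) next
        p_gene <- length(enr_sites[[i]]) / nrow(tt)
        lam <- (enr$fold[i] - 1) * p_gene * config$n_insertions
        n_extra <- if (lam > 0) stats::rpois(1L, lam) else 0L
        if (n_extra > 0L) {
          take <- sample(enr_sites[[i]], n_extra, replace = TRUE)
          rows <- rbind(rows, data.frame(
            sample_id = sid, chrom = tt$chrom[take],
            strand = sample(c("+", "-"), n_extra, replace = TRUE),
            pos = tt$pos[take], stringsAsFactors = FALSE
          ))
        }
      }
    }
    rows$coord <- ifelse(rows$strand == "+", rows$pos + 4L, rows$pos)
    rows$true_diversity <- 1L + stats::rpois(nrow(rows), config$diversity_lambda)
    # collisions (same sample/strand/junction) merge; shear-end counts add
    key <- paste(rows$chrom, rows$strand, rows$coord)
    if (anyDuplicated(key)) {
      div <- tapply(rows$true_diversity, key, sum)
      rows <- rows[!duplicated(key), ]
      rows$true_diversity <- as.integer(div[paste(rows$chrom, rows$strand, rows$coord)])
    }
    res[[s]] <- rows[, c("sample_id", "chrom", "strand", "coord", "true_diversity")]
  }
  truth <- do.call(rbind, res)

  # annotate with the gene span (if any) containing the junction
  truth$gene_id <- NA_character_
  for (ch in unique(truth$chrom)) {
    sp <- spans[spans$chrom == ch, ]
    sp <- sp[order(sp$span_start, sp$gene_id), ]
    ti <- which(truth$chrom == ch)
    if (nrow(sp) == 0L || length(ti) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = truth$coord[ti] + 1L, width = 1L),
      IRanges::IRanges(start = sp$span_start + 1L, end = sp$span_end),
      select = "first"
    )
    truth$gene_id[ti] <- sp$gene_id[ov]
  }
  truth <- truth[order(truth$sample_id, truth$chrom, truth$coord, truth$strand), ]
  rownames(truth) <- NULL
  truth
}
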