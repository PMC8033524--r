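#' Generate a synthetic reference genome and transcript models
#'
#' Draws i.i.d. random chromosome sequences and places non-overlapping genes
#' (one transcript each) with exon/intron structure. A fraction of genes
#' carry no CDS and act as non-coding RNAs; coding genes get 5'UTR, CDS and
#' 3'UTR portions inside their exons. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return list with elements `genome` (named [Biostrings::DNAStringSet]) and
#'   `transcripts` (data.frame as documented in [transcript_table()]).
#' @seealso [write_reference()] to serialize as FASTA + GTF.
#' @export
gen_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  ttaa_n <- Biostrings::vcountPattern("TTAA", genome)
  if (any(ttaa_n < 50L)) {
    stopf("configuration error: chromosome with fewer than 50 TTAA sites (length too small)")
  }

  # round-robin gene placement in equal slots, with clearance for promoters
  chrom_of_gene <- rep(chroms, length.out = config$n_genes)
  margin <- sim_edge_margin() + 2000L
  n_nc <- round(config$noncoding_frac * config$n_genes)
  noncoding_ids <- sample.int(config$n_genes, n_nc)
  tx <- vector("list", config$n_genes)
  for (ch in chroms) {
    idx <- which(chrom_of_gene == ch)
    k <- length(idx)
    if (k == 0L) next
    usable <- config$chrom_length - 2L * margin
    slot <- as.integer(usable %/% k)
    for (j in seq_along(idx)) {
      i <- idx[j]
      slot_start <- margin + (j - 1L) * slot
      max_len <- min(8000L, slot - 4200L)  # keep 2 kb promoter inside the slot
      gene_len <- sample(seq(2000L, max(2000L, max_len), by = 1L), 1L)
      jitter_max <- max(0L, slot - gene_len - 4200L)
      tx_start <- slot_start + 2100L +
        if (jitter_max > 0L) sample.int(jitter_max, 1L) else 0L
      tx_end <- tx_start + gene_len
      strand <- sample(c("+", "-"), 1L)
      ex <- sim_exons(gene_len)
      noncoding <- i %in% noncoding_ids
      if (noncoding) {
        cds <- c(NA_integer_, NA_integer_)
      } else {
        # CDS starts inside the first exon and ends inside the last one,
        # leaving non-empty UTRs on both sides (genomic coordinates)
        first <- ex[1, ]
        last <- ex[nrow(ex), ]
        cds_start <- first[1] + sample.int(max(1L, first[2] - first[1] - 20L), 1L) + 9L
        cds_end <- last[2] - sample.int(max(1L, last[2] - last[1] - 20L), 1L) - 9L
        if (cds_end <= cds_start) {  # single short exon fallback
          cds_start <- first[1] + 10L
          cds_end <- last[2] - 10L
        }
        cds <- c(cds_start, cds_end)
      }
      tx[[i]] <- data.frame(
        gene_id = sprintf("g%03d", i),
        transcript_id = sprintf("g%03d.t1", i),
        chrom = ch, strand = strand,
        tx_start = tx_start, tx_end = tx_end,
        exon_starts = paste(tx_start + ex[, 1], collapse = ","),
        exon_ends = paste(tx_start + ex[, 2], collapse = ","),
        cds_start = tx_start + cds[1], cds_end = tx_start + cds[2],
        stringsAsFactors = FALSE
      )
    }
  }
  transcripts <- do.call(rbind, tx)
  rownames(transcripts) <- NULL
  list(genome = genome, transcripts = transcripts)
}

# exon intervals (0-based, relative to gene start) covering [0, gene_len):
# 2-5 exons separated by introns, first/last flush with the gene ends
sim_exons <- function(gene_len) {
  n_ex <- sample(2:5, 1L)
  n_seg <- 2L * n_ex - 1L
  repeat {
    w <- diff(sort(c(0, stats::runif(n_seg - 1L), 1)))
    widths <- floor(w * gene_len)
    widths[n_seg] <- gene_len - sum(widths[-n_seg])
    if (all(widths >= 60L)) break
  }
  ends <- cumsum(widths)
  starts <- c(0L, ends[-n_seg])
  keep <- seq(1L, n_seg, by = 2L)
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Parse the exon list columns of a transcript table
#'
#' @param tx_row One row of a transcript table.
#' @return integer matrix with columns `start`, `end` (0-based half-open).
#' @export
exon_matrix <- function(tx_row) {
  cbind(
    start = as.integer(strsplit(tx_row$exon_starts, ",")[[1]]),
    end = as.integer(strsplit(tx_row$exon_ends, ",")[[1]])
  )
}

#' Write a synthetic reference as FASTA and GTF
#'
#' @param ref Output of [gen_reference()].
#' @param fasta_path,gtf_path Output file paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, gtf_path) {
  Biostrings::writeXStringSet(ref$genome, fasta_path)
  rtracklayer::export(transcripts_to_granges(ref$transcripts), gtf_path,
                      format = "gtf")
  invisible(c(fasta = fasta_path, gtf = gtf_path))
}

# 0-based half-open table -> 1-based GRanges with transcript/exon/CDS features
transcripts_to_granges <- function(tx) {
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    ex <- exon_matrix(t)
    feat <- data.frame(type = "transcript", start = t$tx_start, end = t$tx_end)
    feat <- rbind(feat, data.frame(type = "exon", start = ex[, 1], end = ex[, 2]))
    if (!is.na(t$cds_start)) {
      cs <- pmax(ex[, 1], t$cds_start)
      ce <- pmin(ex[, 2], t$cds_end)
      keep <- cs < ce
      feat <- rbind(feat, data.frame(type = "CDS", start = cs[keep], end = ce[keep]))
    }
    rows[[i]] <- data.frame(
      chrom = t$chrom, start = feat$start, end = feat$end, strand = t$strand,
      type = feat$type, gene_id = t$gene_id, transcript_id = t$transcript_id,
      stringsAsFactors = FALSE
    )
  }
  d <- do.call(rbind, rows)
  GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
    strand = d$strand,
    type = d$type, gene_id = d$gene_id, transcript_id = d$transcript_id,
    phase = ifelse(d$type == "CDS", 0L, NA_integer_)
  )
}

#' Read transcript models from a GTF/GFF file
#'
#' Reconstructs the package's flat transcript table (0-based half-open
#' coordinates, exon list columns, `NA` CDS for non-coding transcripts) from
#' `transcript`/`exon`/`CDS` features.
#'
#' @param path GTF or GFF3 file.
#' @return Transcript table; see [transcript_table()].
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    stringsAsFactors = FALSE
  )
  d <- d[d$type %in% c("transcript", "exon", "CDS") & !is.na(d$transcript_id), ]
  out <- lapply(split(d, d$transcript_id), function(g) {
    ex <- g[g$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) == 0L) {  # transcript without exon rows: span is one exon
      ex <- g[g$type == "transcript", , drop = FALSE]
    }
    cds <- g[g$type == "CDS", , drop = FALSE]
    data.frame(
      gene_id = g$gene_id[1],
      transcript_id = g$transcript_id[1],
      chrom = g$chrom[1], strand = g$strand[1],
      tx_start = min(ex$start), tx_end = max(ex$end),
      exon_starts = paste(ex$start, collapse = ","),
      exon_ends = paste(ex$end, collapse = ","),
      cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$tx_start, out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Transcript table format
#'
#' The flat transcript representation used throughout the package: one row
#' per transcript with columns `gene_id`, `transcript_id`, `chrom`, `strand`,
#' `tx_start`, `tx_end` (0-based half-open), `exon_starts`/`exon_ends`
#' (comma-separated 0-based coordinates) and `cds_start`/`cds_end` (`NA` for
#' transcripts without an annotated CDS, which the annotation hierarchy
#' treats as non-coding RNAs).
#'
#' @name transcript_table
NULL
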