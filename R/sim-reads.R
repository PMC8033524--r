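#' Simulate splinkerette paired-end libraries from a truth table
#'
#' For each planted insertion, `true_diversity` distinct sonication shear
#' points are drawn (fragment length truncated-Normal, floor
#' `max(20, read_length / 2)`), each unique fragment is sequenced
#' `1 + Poisson(pcr_dup_mean)` times, and reads are emitted as:
#' read 1 = `TAGGGTTAA` + genomic sequence from the insertion junction in
#' the insertion orientation; read 2 = the sequence reading inward from the
#' shear point on the opposite strand. Per-base substitution errors are
#' applied at `seq_error_rate`; a fraction `contaminant_frac` of pairs is
#' replaced by non-transposon pairs whose read 1 lacks the prefix. Quality
#' strings are constant `"I"`.
#'
#' @param ref Output of [gen_reference()].
#' @param truth Truth table from [plant_insertions()].
#' @param config A [sim_config()].
#' @param outdir If non-`NULL`, per-sample `\*_R1.fastq.gz`/`\*_R2.fastq.gz`
#'   files are written there.
#' @return list with `reads` (named list of per-sample data.frames with
#'   columns `id`, `read1`, `read2`), `barcodes` (named character vector),
#'   and `files` (NULL or the written paths).
#' @export
simulate_reads <- function(ref, truth, config, outdir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  prefix <- "TAGGGTTAA"
  rl <- config$read_length
  min_frag <- max(20L, ceiling(rl / 2))
  chrom_seq <- as.character(ref$genome)
  chrom_len <- nchar(chrom_seq)

  samples <- sim_samples(config)
  barcodes <- random_dna(nrow(samples), config$barcode_length)
  while (anyDuplicated(barcodes)) {
    barcodes[duplicated(barcodes)] <-
      random_dna(sum(duplicated(barcodes)), config$barcode_length)
  }
  names(barcodes) <- samples$sample_id

  reads <- list()
  for (sid in samples$sample_id) {
    tr <- truth[truth$sample_id == sid, , drop = FALSE]
    if (nrow(tr) == 0L) {
      reads[[sid]] <- data.frame(id = character(0), read1 = character(0),
                                 read2 = character(0), stringsAsFactors = FALSE)
      next
    }
    frag <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
      d <- tr$true_diversity[i]
      len_ch <- chrom_len[[tr$chrom[i]]]
      coord <- tr$coord[i]
      # room between junction and chromosome end in fragment direction
      room <- if (tr$strand[i] == "+") len_ch - coord else coord
      lens <- integer(0)
      while (length(lens) < d) {  # distinct shear ends; out-of-range resampled
        cand <- as.integer(round(stats::rnorm(2L * d, config$fragment_length_mean,
                                              config$fragment_length_sd)))
        cand <- cand[cand >= min_frag & cand <= room]
        lens <- unique(c(lens, cand))
      }
      lens <- lens[seq_len(d)]
      frag[[i]] <- data.frame(chrom = tr$chrom[i], strand = tr$strand[i],
                              coord = coord, frag_len = lens,
                              stringsAsFactors = FALSE)
    }
    frag <- do.call(rbind, frag)
    copies <- 1L + stats::rpois(nrow(frag), config$pcr_dup_mean)
    frag <- frag[rep(seq_len(nrow(frag)), copies), , drop = FALSE]

    g <- chrom_seq[frag$chrom]
    w1 <- pmin(rl - nchar(prefix), frag$frag_len)
    w2 <- pmin(rl, frag$frag_len)
    plus <- frag$strand == "+"
    r1 <- character(nrow(frag))
    r2 <- character(nrow(frag))
    c0 <- frag$coord
    L <- frag$frag_len
    r1[plus] <- paste0(prefix, substr(g[plus], c0[plus] + 1L, c0[plus] + w1[plus]))
    r2[plus] <- revcomp(substr(g[plus], c0[plus] + L[plus] - w2[plus] + 1L,
                               c0[plus] + L[plus]))
    r1[!plus] <- paste0(prefix, revcomp(substr(g[!plus], c0[!plus] - w1[!plus] + 1L,
                                               c0[!plus])))
    r2[!plus] <- substr(g[!plus], c0[!plus] - L[!plus] + 1L,
                        c0[!plus] - L[!plus] + w2[!plus])

    r1 <- mutate_bases(r1, config$seq_error_rate)
    r2 <- mutate_bases(r2, config$seq_error_rate)

    if (config$contaminant_frac > 0) {
      cont <- stats::runif(length(r1)) < config$contaminant_frac
      if (any(cont)) {
        n <- sum(cont)
        cand <- random_dna(n, rl)
        while (any(startsWith(cand, prefix))) {
          cand[startsWith(cand, prefix)] <-
            random_dna(sum(startsWith(cand, prefix)), rl)
        }
        r1[cont] <- cand
        r2[cont] <- random_dna(n, rl)
      }
    }
    if (config$inline_barcodes) {
      r2 <- paste0(barcodes[[sid]], r2)
    }
    reads[[sid]] <- data.frame(
      id = sprintf("%s_%06d BC:Z:%s", sid, seq_along(r1), barcodes[[sid]]),
      read1 = r1, read2 = r2, stringsAsFactors = FALSE
    )
  }

  files <- NULL
  if (!is.null(outdir)) {
    files <- write_fastq_pairs(reads, outdir)
  }
  list(reads = reads, barcodes = barcodes, files = files)
}

#' Write paired FASTQ files (one pair of files per sample)
#'
#' @param reads Named list of data.frames with `id`, `read1`, `read2`.
#' @param outdir Output directory (created if missing).
#' @param compress Write gzipped files (default `TRUE`).
#' @return data.frame with `sample_id`, `r1`, `r2` paths.
#' @export
write_fastq_pairs <- function(reads, outdir, compress = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  out <- lapply(names(reads), function(sid) {
    df <- reads[[sid]]
    r1 <- file.path(outdir, paste0(sid, "_R1", ext))
    r2 <- file.path(outdir, paste0(sid, "_R2", ext))
    for (side in c("read1", "read2")) {
      x <- Biostrings::DNAStringSet(df[[side]])
      names(x) <- df$id
      q <- Biostrings::BStringSet(strrep("I", nchar(df[[side]])))
      Biostrings::writeXStringSet(x, if (side == "read1") r1 else r2,
                                  format = "fastq", compress = compress,
                                  qualities = q)
    }
    data.frame(sample_id = sid, r1 = r1, r2 = r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a pair of FASTQ files into the in-memory pair table
#'
#' @param r1,r2 FASTQ paths (optionally gzipped).
#' @return data.frame with columns `id`, `read1`, `read2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  a <- Biostrings::readDNAStringSet(r1, format = "fastq")
  b <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(a) != length(b)) {
    stopf("R1 and R2 have different numbers of reads (%d vs %d)",
          length(a), length(b))
  }
  data.frame(id = names(a), read1 = as.character(a), read2 = as.character(b),
             stringsAsFactors = FALSE)
}

#' Write a truth table as TSV
#' @param truth Truth table from [plant_insertions()].
#' @param path Output path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
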