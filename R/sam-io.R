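#' Write aligned pairs as a SAM file
#'
#' Serializes the `AlignedPair` table as minimal paired-end SAM records
#' (two records per pair, proper-pair flags, `*` sequences). Read widths are
#' capped at the fragment length so both mates stay inside the fragment.
#'
#' @param aligned data.frame from [align_pairs()] (`$pairs`).
#' @param genome Named [Biostrings::DNAStringSet] (for `@SQ` headers).
#' @param path Output `.sam` path.
#' @param read_length Nominal read width used for the records.
#' @return invisibly, `path`.
#' @export
write_alignments_sam <- function(aligned, genome, path, read_length = 100L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), lengths(genome)))
  lines <- character(0)
  if (nrow(aligned)) {
    w1 <- pmin(read_length, aligned$insert_size)
    w2 <- w1
    plus <- aligned$strand == "+"
    # 0-based leftmost of each record
    r1_pos <- ifelse(plus, aligned$r1_start, aligned$r1_start - w1)
    r2_pos <- ifelse(plus, aligned$shear_end - w2, aligned$shear_end)
    f1 <- ifelse(plus, 99L, 83L)    # paired, proper, first-in-pair
    f2 <- ifelse(plus, 147L, 163L)  # paired, proper, second-in-pair
    tlen <- ifelse(plus, aligned$insert_size, -aligned$insert_size)
    qname <- gsub("[ \t]", "_", aligned$id)
    rec1 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                    qname, f1, aligned$chrom, r1_pos + 1L, w1, r2_pos + 1L, tlen)
    rec2 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                    qname, f2, aligned$chrom, r2_pos + 1L, w2, r1_pos + 1L, -tlen)
    lines <- as.vector(rbind(rec1, rec2))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read aligned pairs from SAM/BAM
#'
#' Converts properly paired primary alignments to the `AlignedPair` table.
#' Secondary and supplementary records are ignored; orphan mates are skipped
#' with a warning. `r1_start` follows the junction convention: the leftmost
#' aligned base of read 1 on `+`, one past its rightmost aligned base on `-`.
#'
#' @param path A `.sam` or `.bam` file with paired records.
#' @return list with `pairs` (as from [align_pairs()]) and `stats`
#'   (`records`, `orphans`).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    flag = flags)
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  empty <- data.frame(id = character(0), chrom = character(0),
                      strand = character(0), r1_start = integer(0),
                      shear_end = integer(0), insert_size = integer(0),
                      unique = logical(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(pairs = empty, stats = list(records = 0L, orphans = 0L)))
  }
  width <- cigar_ref_width(b$cigar)
  d <- data.frame(
    qname = b$qname, flag = b$flag, chrom = as.character(b$rname),
    strand = as.character(b$strand), pos0 = b$pos - 1L, width = width,
    stringsAsFactors = FALSE)
  d$is_r1 <- bitwAnd(d$flag, 64L) > 0L

  by_q <- split(seq_len(n), d$qname)
  orphans <- 0L
  rows <- vector("list", length(by_q))
  for (k in seq_along(by_q)) {
    ii <- by_q[[k]]
    r1 <- ii[d$is_r1[ii]]
    r2 <- ii[!d$is_r1[ii]]
    if (length(r1) != 1L || length(r2) != 1L) {
      orphans <- orphans + 1L
      next
    }
    strand <- d$strand[r1]
    r1_start <- if (strand == "+") d$pos0[r1] else d$pos0[r1] + d$width[r1]
    shear <- if (d$strand[r2] == "-") d$pos0[r2] + d$width[r2] else d$pos0[r2]
    rows[[k]] <- data.frame(
      id = d$qname[r1], chrom = d$chrom[r1], strand = strand,
      r1_start = r1_start, shear_end = shear,
      insert_size = abs(shear - r1_start), unique = TRUE,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$chrom, out$r1_start, out$strand, out$id), ]
  rownames(out) <- NULL
  if (orphans > 0L) warnf("%d orphan mate group(s) skipped", orphans)
  list(pairs = out, stats = list(records = n, orphans = orphans))
}

# reference-consumed width of simple CIGAR strings
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops)) return(NA_integer_)
    lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
    type <- sub("\\d+", "", ops)
    sum(lens[type %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
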