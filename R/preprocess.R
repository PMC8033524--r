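#' Trim the transposon-derived prefix from read 1
#'
#' Read pairs whose first read begins with the expected transposon-derived
#' sequence have that prefix removed; all other pairs are discarded and
#' counted. Around 1% of pairs are expected to fail the prefix check in a
#' typical splinkerette library.
#'
#' @param pairs data.frame with columns `read1`, `read2` (and optionally
#'   `id`), as produced by [read_fastq_pairs()] or [simulate_reads()].
#' @param prefix Expected transposon-derived prefix on read 1.
#' @return list with `pairs` (trimmed, kept pairs) and `stats`
#'   (list: `total`, `kept`, `discarded`, `fraction_discarded`).
#' @export
trim_prefix <- function(pairs, prefix = "TAGGGTTAA") {
  if (!nzchar(prefix) || grepl("[^ACGT]", prefix)) {
    stopf("prefix must be a non-empty uppercase ACGT string")
  }
  total <- nrow(pairs)
  if (total == 0L) {
    return(list(pairs = pairs,
                stats = list(total = 0L, kept = 0L, discarded = 0L,
                             fraction_discarded = 0)))
  }
  keep <- startsWith(pairs$read1, prefix)
  out <- pairs[keep, , drop = FALSE]
  out$read1 <- substring(out$read1, nchar(prefix) + 1L)
  rownames(out) <- NULL
  list(
    pairs = out,
    stats = list(total = total, kept = sum(keep), discarded = sum(!keep),
                 fraction_discarded = sum(!keep) / total)
  )
}
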