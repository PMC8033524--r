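# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based, half-open; 1-based coordinates appear only at
# FASTA/GTF/SAM/BED boundaries.

#' Reverse-complement character sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substr on 0-based half-open coordinates
substr0 <- function(x, start0, end0) {
  substr(x, start0 + 1L, end0)
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

# introduce independent per-base substitution errors at `rate`
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  widths <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), widths, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(widths[i], nerr[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
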