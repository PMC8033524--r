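#' Align trimmed read pairs with a uniqueness contract
#'
#' Built-in aligner for small (simulated) references. A pair is reported iff
#' read 1 matches exactly one genomic locus at its best mismatch stratum and
#' its mate has exactly one consistent placement (opposite strand, correct
#' side, within `max_insert`). Matching requires an exact seed of
#' `seed_length` nt at the 5' end of each read and tolerates up to
#' `max_mismatch` substitutions over the full read; no gaps. This reproduces
#' the uniqueness semantics of a `-m 1 --best --strata --maxins 1000`
#' short-read alignment rather than its exact parameterization.
#'
#' Coordinates follow the junction convention: `r1_start` is the boundary
#' between the (trimmed-away) transposon TTAA and the genomic sequence in
#' read-1 orientation -- on `+` the 0-based position of the first aligned
#' base, on `-` one past the most-5' aligned base. `shear_end` is the
#' corresponding outer boundary of the sonication fragment.
#'
#' @param pairs data.frame with `read1` (prefix-trimmed), `read2`, and
#'   optionally `id`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param max_insert Maximum between-pair distance (bp).
#' @param seed_length Exact-match seed length at each read's 5' end.
#' @param max_mismatch Mismatch budget over the full read.
#' @return list with `pairs`: data.frame(`id`, `chrom`, `strand`,
#'   `r1_start`, `shear_end`, `insert_size`, `unique`) and `stats`: counts of
#'   input, short, unmapped, multi-mapping, mate-failed and reported pairs.
#' @export
align_pairs <- function(pairs, genome, max_insert = 1000L,
                        seed_length = 20L, max_mismatch = 1L) {
  n <- nrow(pairs)
  stats <- list(input = n, too_short = 0L, unmapped = 0L, multimapped = 0L,
                mate_failed = 0L, reported = 0L)
  empty <- data.frame(id = character(0), chrom = character(0),
                      strand = character(0), r1_start = integer(0),
                      shear_end = integer(0), insert_size = integer(0),
                      unique = logical(0), stringsAsFactors = FALSE)
  if (n == 0L) return(list(pairs = empty, stats = stats))

  ids <- pairs$id %||% as.character(seq_len(n))
  ok_len <- nchar(pairs$read1) >= seed_length & nchar(pairs$read2) >= seed_length
  clean <- !grepl("[^ACGT]", substr(pairs$read1, 1L, seed_length))
  usable <- which(ok_len & clean)
  stats$too_short <- sum(!ok_len)
  if (length(usable) == 0L) {
    stats$unmapped <- n - stats$too_short
    return(list(pairs = empty, stats = stats))
  }

  seeds <- Biostrings::DNAStringSet(substr(pairs$read1[usable], 1L, seed_length))
  pd_fwd <- Biostrings::PDict(seeds)
  pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(seeds))

  # candidate loci per usable read: junction coordinate + strand per chrom
  cand <- list()
  for (ch in names(genome)) {
    subj <- genome[[ch]]
    mf <- Biostrings::matchPDict(pd_fwd, subj)
    mr <- Biostrings::matchPDict(pd_rev, subj)
    sf <- BiocGenerics::start(mf)   # IntegerList, 1-based seed starts
    sr <- BiocGenerics::start(mr)
    nf <- S4Vectors::elementNROWS(sf)
    nr <- S4Vectors::elementNROWS(sr)
    if (sum(nf) > 0L) {
      cand[[paste0(ch, "+")]] <- data.frame(
        read = rep(usable, nf), chrom = ch, strand = "+",
        coord = unlist(sf, use.names = FALSE) - 1L, stringsAsFactors = FALSE)
    }
    if (sum(nr) > 0L) {
      cand[[paste0(ch, "-")]] <- data.frame(
        read = rep(usable, nr), chrom = ch, strand = "-",
        coord = unlist(sr, use.names = FALSE) - 1L + seed_length,
        stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else NULL
  if (is.null(cand)) {
    stats$unmapped <- n - stats$too_short
    return(list(pairs = empty, stats = stats))
  }

  # verify candidates over the full read (<= max_mismatch, no gaps)
  chrom_seq <- as.character(genome)
  chrom_len <- nchar(chrom_seq)
  w <- nchar(pairs$read1)[cand$read]
  g <- chrom_seq[cand$chrom]
  len <- chrom_len[cand$chrom]
  plus <- cand$strand == "+"
  in_bounds <- ifelse(plus, cand$coord + w <= len, cand$coord - w >= 0L)
  cand <- cand[in_bounds, , drop = FALSE]
  w <- w[in_bounds]; g <- g[in_bounds]; plus <- plus[in_bounds]
  ref_seq <- ifelse(plus,
                    substr(g, cand$coord + 1L, cand$coord + w),
                    substr(g, cand$coord - w + 1L, cand$coord))
  read_seq <- pairs$read1[cand$read]
  read_seq[!plus] <- revcomp(read_seq[!plus])
  cand$mm <- count_mismatches(read_seq, ref_seq)
  cand <- cand[cand$mm <= max_mismatch, , drop = FALSE]

  # best-stratum uniqueness of read 1
  res <- list()
  by_read <- split(cand, cand$read)
  mapped_reads <- as.integer(names(by_read))
  stats$unmapped <- n - stats$too_short - length(mapped_reads)
  for (k in seq_along(by_read)) {
    cc <- by_read[[k]]
    best <- cc[cc$mm == min(cc$mm), , drop = FALSE]
    if (nrow(best) != 1L) {
      stats$multimapped <- stats$multimapped + 1L
      next
    }
    i <- best$read[1]
    mate <- place_mate(pairs$read2[i], chrom_seq[[best$chrom]], best$strand,
                       best$coord, max_insert, max_mismatch)
    if (is.null(mate)) {
      stats$mate_failed <- stats$mate_failed + 1L
      next
    }
    ins <- abs(mate - best$coord)
    if (ins == 0L || ins > max_insert) {
      stats$mate_failed <- stats$mate_failed + 1L
      next
    }
    res[[length(res) + 1L]] <- data.frame(
      id = ids[i], chrom = best$chrom, strand = best$strand,
      r1_start = best$coord, shear_end = mate, insert_size = ins,
      unique = TRUE, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else empty
  rownames(out) <- NULL
  stats$reported <- nrow(out)
  list(pairs = out, stats = stats)
}

# shear-end coordinate of the mate, or NULL when there is no unique
# best-stratum placement on the expected side
place_mate <- function(read2, chrom, strand, coord, max_insert, max_mismatch) {
  w2 <- nchar(read2)
  len <- nchar(chrom)
  if (strand == "+") {
    lo <- coord                      # fragment extends to the right
    hi <- min(len, coord + max_insert)
    if (hi - lo < w2) return(NULL)
    window <- Biostrings::DNAString(substr(chrom, lo + 1L, hi))
    pat <- Biostrings::DNAString(revcomp(read2))
  } else {
    lo <- max(0L, coord - max_insert)  # fragment extends to the left
    hi <- coord
    if (hi - lo < w2) return(NULL)
    window <- Biostrings::DNAString(substr(chrom, lo + 1L, hi))
    pat <- Biostrings::DNAString(read2)
  }
  hit <- NULL
  for (mm in 0:max_mismatch) {  # best stratum first
    m <- Biostrings::matchPattern(pat, window, max.mismatch = mm)
    if (length(m) == 1L) {
      hit <- BiocGenerics::start(m) - 1L + lo
      break
    }
    if (length(m) > 1L) return(NULL)
  }
  if (is.null(hit)) return(NULL)
  if (strand == "+") hit + w2 else hit
}

# elementwise Hamming distance between equal-length strings
count_mismatches <- function(a, b) {
  if (length(a) == 0L) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}
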