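#' Collapse aligned pairs into integration sites
#'
#' Pairs are grouped by `(chrom, strand, r1_start)`; each group becomes one
#' integration site at `coord = r1_start`. The site's `diversity` is the
#' number of distinct shear-end coordinates in the group -- identical
#' fragments arising from PCR duplication collapse to a single shear end, so
#' diversity is invariant under any amount of read duplication --
#' and `raw_reads` is the group size. `upstream4` is the genomic 4-mer on
#' the read-1 strand immediately upstream of the junction (`"NNNN"` when the
#' junction is closer than 4 bp to the chromosome edge, which the motif
#' filter then rejects).
#'
#' @param aligned data.frame from [align_pairs()] (`$pairs`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param sample_id Sample label recorded on every site.
#' @return data.frame with columns `sample_id`, `chrom`, `strand`, `coord`,
#'   `upstream4`, `diversity`, `raw_reads`, sorted by chrom, coord, strand.
#' @export
call_sites <- function(aligned, genome, sample_id) {
  if (nrow(aligned) == 0L) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      strand = character(0), coord = integer(0),
                      upstream4 = character(0), diversity = integer(0),
                      raw_reads = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(aligned$chrom, aligned$strand, aligned$r1_start, sep = "\r")
  grp <- split(seq_len(nrow(aligned)), key)
  first <- vapply(grp, `[`, integer(1), 1L)
  sites <- data.frame(
    sample_id = sample_id,
    chrom = aligned$chrom[first],
    strand = aligned$strand[first],
    coord = aligned$r1_start[first],
    diversity = vapply(grp, function(ii) {
      length(unique(aligned$shear_end[ii]))
    }, integer(1)),
    raw_reads = lengths(grp),
    stringsAsFactors = FALSE
  )
  sites$upstream4 <- upstream_4mer(sites, genome)
  sites <- sites[order(sites$chrom, sites$coord, sites$strand),
                 c("sample_id", "chrom", "strand", "coord", "upstream4",
                   "diversity", "raw_reads")]
  rownames(sites) <- NULL
  sites
}

# genomic 4-mer directly upstream of the junction, on the read-1 strand:
# + strand genome[coord-4, coord); - strand revcomp(genome[coord, coord+4))
upstream_4mer <- function(sites, genome) {
  chrom_seq <- as.character(genome)
  chrom_len <- nchar(chrom_seq)
  g <- chrom_seq[sites$chrom]
  len <- chrom_len[sites$chrom]
  out <- character(nrow(sites))
  plus <- sites$strand == "+"
  ok_p <- plus & sites$coord >= 4L
  ok_m <- !plus & sites$coord + 4L <= len
  out[ok_p] <- substr(g[ok_p], sites$coord[ok_p] - 3L, sites$coord[ok_p])
  out[ok_m] <- revcomp(substr(g[ok_m], sites$coord[ok_m] + 1L,
                              sites$coord[ok_m] + 4L))
  out[!(ok_p | ok_m)] <- "NNNN"
  out
}

#' Filter integration sites on the expected upstream TTAA motif
#'
#' @param sites data.frame from [call_sites()].
#' @param genome Optional genome to (re)compute `upstream4` from.
#' @return list with `kept` (upstream 4-mer is `TTAA`) and `rejected`
#'   (everything else, returned for QC).
#' @export
filter_ttaa <- function(sites, genome = NULL) {
  if (!is.null(genome)) {
    sites$upstream4 <- upstream_4mer(sites, genome)
  }
  keep <- sites$upstream4 == "TTAA"
  list(kept = sites[keep, , drop = FALSE],
       rejected = sites[!keep, , drop = FALSE])
}

#' Write integration sites as BED6+2
#'
#' Columns: chrom, start (= coord), end (= coord + 1), name
#' (`sample:index`), score (= diversity), strand, upstream4, raw_reads.
#'
#' @param sites data.frame from [call_sites()].
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(
    chrom = sites$chrom,
    start = sites$coord,
    end = sites$coord + 1L,
    name = paste0(sites$sample_id, ":", seq_len(nrow(sites))),
    score = sites$diversity,
    strand = sites$strand,
    upstream4 = sites$upstream4,
    raw_reads = sites$raw_reads
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read integration sites from a BED6+2 file written by [write_sites_bed()]
#' @param path BED path.
#' @param sample_id Optional sample label override (default: from names).
#' @return Site table as from [call_sites()].
#' @export
read_sites_bed <- function(path, sample_id = NULL) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand",
                  "upstream4", "raw_reads")[seq_len(ncol(bed))]
  data.frame(
    sample_id = sample_id %||% sub(":.*$", "", bed$name),
    chrom = bed$chrom, strand = bed$strand, coord = bed$start,
    upstream4 = bed$upstream4, diversity = bed$score,
    raw_reads = bed$raw_reads, stringsAsFactors = FALSE
  )
}
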