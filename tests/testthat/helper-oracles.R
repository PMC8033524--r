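# Independent oracles used to check package operations. These deliberately
# use naive brute-force logic, not the package's code paths.

# count of TTAA occurrences by sliding-window scan
oracle_ttaa_count <- function(seq) {
  n <- 0L
  for (i in seq_len(nchar(seq) - 3L)) {
    if (substr(seq, i, i + 3L) == "TTAA") n <- n + 1L
  }
  n
}

# per-position classification by exhaustive per-transcript checks
oracle_classify <- function(coord, transcripts, promoter = 2000L) {
  tx <- transcripts[order(transcripts$chrom, transcripts$tx_start,
                          transcripts$transcript_id), , drop = FALSE]
  in_type <- function(t, p, type) {
    if (is.na(t$cds_start)) {
      return(type == "ncRNA" && p >= t$tx_start && p < t$tx_end)
    }
    if (type == "ncRNA") return(FALSE)
    es <- as.integer(strsplit(t$exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(t$exon_ends, ",")[[1]])
    exonic <- any(p >= es & p < ee)
    if (type == "intron") {
      return(!exonic && p >= t$tx_start && p < t$tx_end)
    }
    if (!exonic) return(FALSE)
    region <- if (p < t$cds_start) {
      if (t$strand == "+") "5UTR" else "3UTR"
    } else if (p >= t$cds_end) {
      if (t$strand == "+") "3UTR" else "5UTR"
    } else "CDS"
    region == type
  }
  overlapping <- which(tx$tx_start <= coord & coord < tx$tx_end)
  if (length(overlapping) == 0L) {
    for (i in seq_len(nrow(tx))) {
      t <- tx[i, ]
      hit <- if (t$strand == "+") {
        coord >= t$tx_start - promoter && coord < t$tx_start
      } else {
        coord >= t$tx_end && coord < t$tx_end + promoter
      }
      if (hit) {
        return(list(category = "promoter", gene_id = t$gene_id))
      }
    }
    return(list(category = "intergenic", gene_id = NA_character_))
  }
  for (type in c("5UTR", "CDS", "3UTR", "intron", "ncRNA")) {
    for (i in overlapping) {
      if (in_type(tx[i, ], coord, type)) {
        return(list(category = type, gene_id = tx$gene_id[i]))
      }
    }
  }
  stop("oracle: unclassifiable position")  # cannot happen
}

# brute-force basal+extension regulatory domains
oracle_great_domains <- function(transcripts, basal_up = 5000L,
                                 basal_down = 1000L, max_ext = 10000L) {
  genes <- split(transcripts, transcripts$gene_id)
  tab <- do.call(rbind, lapply(genes, function(g) {
    tss <- if (g$strand[1] == "+") min(g$tx_start) else max(g$tx_end)
    bs <- if (g$strand[1] == "+") tss - basal_up else tss - basal_down
    be <- if (g$strand[1] == "+") tss + basal_down else tss + basal_up
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], tss = tss,
               basal_start = max(0L, bs), basal_end = be,
               stringsAsFactors = FALSE)
  }))
  tab$ext_start <- NA_real_
  tab$ext_end <- NA_real_
  for (i in seq_len(nrow(tab))) {
    limit_l <- 0; overlap_l <- FALSE
    limit_r <- Inf; overlap_r <- FALSE
    for (j in seq_len(nrow(tab))) {
      if (j == i || tab$chrom[j] != tab$chrom[i]) next
      if (tab$basal_start[j] < tab$basal_start[i]) {
        if (tab$basal_end[j] >= tab$basal_start[i]) overlap_l <- TRUE
        else limit_l <- max(limit_l, tab$basal_end[j])
      } else {
        if (tab$basal_start[j] <= tab$basal_end[i]) overlap_r <- TRUE
        else limit_r <- min(limit_r, tab$basal_start[j])
      }
    }
    tab$ext_start[i] <- if (overlap_l) tab$basal_start[i] else
      max(tab$basal_start[i] - max_ext, limit_l)
    tab$ext_end[i] <- if (overlap_r) tab$basal_end[i] else
      min(tab$basal_end[i] + max_ext, limit_r)
  }
  tab
}

oracle_great_assoc <- function(peaks, transcripts, ...) {
  dom <- oracle_great_domains(transcripts, ...)
  out <- character(0)
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    for (j in seq_len(nrow(dom))) {
      if (dom$chrom[j] == peaks$chrom[i] &&
          dom$ext_start[j] <= mid && mid < dom$ext_end[j]) {
        out <- c(out, paste(peaks$peak_id[i], dom$gene_id[j]))
      }
    }
  }
  sort(out)
}

# exact two-sided Mann-Whitney p by direct enumeration over value labelings
# (pairwise-count U, no ranks involved)
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">"))
  U <- u_of(x, y)
  combs <- utils::combn(length(pooled), nx)
  Us <- apply(combs, 2L, function(ii) u_of(pooled[ii], pooled[-ii]))
  p_one <- min(mean(Us <= U), mean(Us >= U))
  list(U = U, p = min(1, 2 * p_one))
}

# compact transcript-table constructor for toys
toy_tx <- function(gene_id, chrom, strand, tx_start, tx_end,
                   exon_starts = tx_start, exon_ends = tx_end,
                   cds_start = NA, cds_end = NA,
                   transcript_id = paste0(gene_id, ".t1")) {
  data.frame(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
             strand = strand, tx_start = tx_start, tx_end = tx_end,
             exon_starts = paste(exon_starts, collapse = ","),
             exon_ends = paste(exon_ends, collapse = ","),
             cds_start = cds_start, cds_end = cds_end,
             stringsAsFactors = FALSE)
}
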