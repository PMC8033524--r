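#' Derive typed genomic regions from transcript models
#'
#' Coding transcripts contribute strand-aware `5UTR`, `CDS` and `3UTR`
#' pieces (exon intersected with the CDS interval and what lies outside it)
#' plus `intron` gaps; transcripts without an annotated CDS contribute one
#' `ncRNA` region spanning the whole transcript.
#'
#' @param transcripts Transcript table (see [transcript_table()]).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `type`, `gene_id`, `transcript_id`, `gene_strand`, `tx_order` (the
#'   deterministic scan rank by chrom, tx_start, transcript_id).
#' @export
transcript_regions <- function(transcripts) {
  tx <- transcripts[order(transcripts$chrom, transcripts$tx_start,
                          transcripts$transcript_id), , drop = FALSE]
  rows <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    ex <- exon_matrix(t)
    if (is.na(t$cds_start)) {
      reg <- data.frame(start = t$tx_start, end = t$tx_end, type = "ncRNA")
    } else {
      pieces <- list()
      for (j in seq_len(nrow(ex))) {
        es <- ex[j, 1]; ee <- ex[j, 2]
        segs <- rbind(
          c(es, min(ee, t$cds_start)),                    # left of CDS
          c(max(es, t$cds_start), min(ee, t$cds_end)),    # inside CDS
          c(max(es, t$cds_end), ee)                        # right of CDS
        )
        kinds_plus <- c("5UTR", "CDS", "3UTR")
        kinds <- if (t$strand == "+") kinds_plus else rev(kinds_plus)
        ok <- segs[, 1] < segs[, 2]
        if (any(ok)) {
          pieces[[length(pieces) + 1L]] <-
            data.frame(start = segs[ok, 1], end = segs[ok, 2], type = kinds[ok])
        }
      }
      if (nrow(ex) > 1L) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          start = ex[-nrow(ex), 2], end = ex[-1, 1], type = "intron")
      }
      reg <- do.call(rbind, pieces)
    }
    rows[[i]] <- data.frame(
      chrom = t$chrom, start = reg$start, end = reg$end, type = reg$type,
      gene_id = t$gene_id, transcript_id = t$transcript_id,
      gene_strand = t$strand, tx_order = i, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Strand-aware promoter windows (2 kb upstream of each transcript start)
#'
#' @param transcripts Transcript table.
#' @param width Window size in bp upstream of the TSS.
#' @return data.frame like [transcript_regions()] with `type = "promoter"`.
#' @export
promoter_regions <- function(transcripts, width = 2000L) {
  tx <- transcripts[order(transcripts$chrom, transcripts$tx_start,
                          transcripts$transcript_id), , drop = FALSE]
  plus <- tx$strand == "+"
  data.frame(
    chrom = tx$chrom,
    start = pmax(0L, ifelse(plus, tx$tx_start - width, tx$tx_end)),
    end = ifelse(plus, tx$tx_start, tx$tx_end + width),
    type = "promoter", gene_id = tx$gene_id,
    transcript_id = tx$transcript_id, gene_strand = tx$strand,
    tx_order = seq_len(nrow(tx)), stringsAsFactors = FALSE)
}

region_priority <- c("5UTR" = 1L, "CDS" = 2L, "3UTR" = 3L,
                     "intron" = 4L, "ncRNA" = 5L)

#' Classify integration sites against the gene annotation hierarchy
#'
#' Each site (a 1-bp point at its junction coordinate) is matched against
#' transcript regions on any strand. Sites overlapping no transcript are
#' `promoter` when inside any 2-kb strand-aware upstream window, else
#' `intergenic`. All other sites take the first matching region type in the
#' fixed order 5UTR, CDS, 3UTR, intron, ncRNA; ties between transcripts are
#' broken by the deterministic scan order (chrom, tx_start, transcript_id).
#' Orientation is `same` when the site strand equals the assigned gene's
#' strand (`NA` for intergenic sites). Intergenic sites carry their flanking
#' gene pair (`.` at chromosome ends) and are grouped under that ordered
#' pair; all other sites (promoter included) group under their gene.
#'
#' @param sites Site table from [call_sites()] (needs `chrom`, `strand`,
#'   `coord`; extra columns such as `sample_id` and `diversity` pass
#'   through).
#' @param transcripts Transcript table.
#' @param promoter_width Promoter window size (bp).
#' @return `sites` with added columns `category`, `gene_id`, `gene_left`,
#'   `gene_right`, `orientation`, `group_key`.
#' @export
classify_sites <- function(sites, transcripts, promoter_width = 2000L) {
  n <- nrow(sites)
  out <- sites
  out$category <- rep("intergenic", n)
  out$gene_id <- rep(NA_character_, n)
  out$gene_left <- rep(NA_character_, n)
  out$gene_right <- rep(NA_character_, n)
  out$orientation <- rep(NA_character_, n)
  if (n == 0L) {
    out$group_key <- character(0)
    return(out)
  }

  regions <- transcript_regions(transcripts)
  promoters <- promoter_regions(transcripts, width = promoter_width)
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$coord + 1L, width = 1L))

  pick_first <- function(hits_df) {
    # order: priority rank then transcript scan order
    o <- order(hits_df$rank, hits_df$tx_order)
    hits_df[o[1], ]
  }

  reg_gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  ov <- GenomicRanges::findOverlaps(site_gr, reg_gr, ignore.strand = TRUE)
  if (length(ov)) {
    hit_df <- data.frame(
      site = S4Vectors::queryHits(ov),
      type = regions$type[S4Vectors::subjectHits(ov)],
      rank = region_priority[regions$type[S4Vectors::subjectHits(ov)]],
      gene_id = regions$gene_id[S4Vectors::subjectHits(ov)],
      gene_strand = regions$gene_strand[S4Vectors::subjectHits(ov)],
      tx_order = regions$tx_order[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
    for (s in unique(hit_df$site)) {
      h <- pick_first(hit_df[hit_df$site == s, , drop = FALSE])
      out$category[s] <- h$type
      out$gene_id[s] <- h$gene_id
      out$orientation[s] <- if (sites$strand[s] == h$gene_strand) "same" else "opposite"
    }
  }

  # sites without any transcript overlap: promoter windows, then intergenic
  free <- which(out$category == "intergenic")
  if (length(free)) {
    prom_gr <- GenomicRanges::GRanges(
      seqnames = promoters$chrom,
      ranges = IRanges::IRanges(start = promoters$start + 1L,
                                end = promoters$end))
    ovp <- GenomicRanges::findOverlaps(site_gr[free], prom_gr,
                                       ignore.strand = TRUE)
    if (length(ovp)) {
      hit_df <- data.frame(
        site = free[S4Vectors::queryHits(ovp)],
        gene_id = promoters$gene_id[S4Vectors::subjectHits(ovp)],
        gene_strand = promoters$gene_strand[S4Vectors::subjectHits(ovp)],
        rank = 0L,
        tx_order = promoters$tx_order[S4Vectors::subjectHits(ovp)],
        stringsAsFactors = FALSE)
      for (s in unique(hit_df$site)) {
        h <- pick_first(hit_df[hit_df$site == s, , drop = FALSE])
        out$category[s] <- "promoter"
        out$gene_id[s] <- h$gene_id
        out$orientation[s] <- if (sites$strand[s] == h$gene_strand) "same" else "opposite"
      }
    }
  }

  # flanking gene pair for the remaining intergenic sites
  inter <- which(out$category == "intergenic")
  if (length(inter)) {
    spans <- gene_spans(transcripts, promoter = 0L)
    for (ch in unique(out$chrom[inter])) {
      ii <- inter[out$chrom[inter] == ch]
      sp <- spans[spans$chrom == ch, , drop = FALSE]
      if (nrow(sp) == 0L) {
        out$gene_left[ii] <- "."
        out$gene_right[ii] <- "."
        next
      }
      for (s in ii) {
        coord <- out$coord[s]
        left <- sp[sp$end <= coord, , drop = FALSE]
        right <- sp[sp$start > coord, , drop = FALSE]
        out$gene_left[s] <- if (nrow(left)) {
          left$gene_id[order(-left$end, left$gene_id)][1]
        } else "."
        out$gene_right[s] <- if (nrow(right)) {
          right$gene_id[order(right$start, right$gene_id)][1]
        } else "."
      }
    }
  }

  out$group_key <- ifelse(is.na(out$gene_id),
                          paste0(out$gene_left, "|", out$gene_right),
                          out$gene_id)
  out
}

#' Group annotated sites by gene (or flanking-gene pair)
#'
#' @param annotated Output of [classify_sites()].
#' @return Named list of row indices, one element per `group_key`; the
#'   groups partition the input.
#' @export
group_by_gene <- function(annotated) {
  split(seq_len(nrow(annotated)), annotated$group_key)
}
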