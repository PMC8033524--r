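#' Basal-plus-extension peak-to-gene association
#'
#' Each gene receives a strand-aware basal regulatory domain around its TSS
#' (`basal_up` bp upstream, `basal_down` bp downstream). Basal domains are
#' then extended on both sides up to the nearest neighbouring basal domain,
#' capped at `max_ext` bp beyond the basal edge; when a neighbour's basal
#' domain already overlaps, no extension happens on that side. A peak is
#' associated with every gene whose regulatory domain contains the peak's
#' midpoint, so an isolated gene can capture peaks up to
#' `basal_up + max_ext` bp upstream.
#'
#' For genes with several transcripts the 5'-most TSS is used. Curated
#' regulatory domains (a feature of the original association tool's
#' database) are not supported.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `peak_id`.
#' @param transcripts Transcript table.
#' @param basal_up,basal_down Basal domain extent (bp) upstream/downstream
#'   of the TSS.
#' @param max_ext Maximum extension (bp) beyond each basal edge.
#' @return list with `assoc` (data.frame `peak_id`, `gene_id`) and
#'   `domains` (per-gene basal and extended domain coordinates).
#' @export
great_associate <- function(peaks, transcripts, basal_up = 5000L,
                            basal_down = 1000L, max_ext = 10000L) {
  dom <- great_domains(transcripts, basal_up, basal_down, max_ext)
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- paste0("peak", seq_len(nrow(peaks)))
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    hit <- dom$gene_id[dom$chrom == peaks$chrom[i] &
                         dom$ext_start <= mid[i] & mid[i] < dom$ext_end]
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[i], gene_id = sort(hit),
        stringsAsFactors = FALSE)
    }
  }
  assoc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_id = character(0), gene_id = character(0),
               stringsAsFactors = FALSE)
  rownames(assoc) <- NULL
  list(assoc = assoc, domains = dom)
}

#' Per-gene basal and extended regulatory domains
#'
#' @inheritParams great_associate
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `basal_start`, `basal_end`, `ext_start`, `ext_end` (0-based half-open).
#' @export
great_domains <- function(transcripts, basal_up = 5000L, basal_down = 1000L,
                          max_ext = 10000L) {
  genes <- lapply(split(transcripts, transcripts$gene_id), function(g) {
    # 5'-most TSS over the gene's transcripts (junction coordinate)
    tss <- if (g$strand[1] == "+") min(g$tx_start) else max(g$tx_end)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], tss = tss, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, genes)
  plus <- d$strand == "+"
  d$basal_start <- pmax(0L, ifelse(plus, d$tss - basal_up, d$tss - basal_down))
  d$basal_end <- ifelse(plus, d$tss + basal_down, d$tss + basal_up)
  d$ext_start <- d$basal_start
  d$ext_end <- d$basal_end
  for (ch in unique(d$chrom)) {
    ii <- which(d$chrom == ch)
    for (i in ii) {
      others <- setdiff(ii, i)
      left_ends <- d$basal_end[others][d$basal_start[others] < d$basal_start[i]]
      if (length(left_ends) && max(left_ends) >= d$basal_start[i]) {
        limit_l <- d$basal_start[i]  # neighbour overlaps: no gap to fill
      } else {
        limit_l <- max(0L, if (length(left_ends)) max(left_ends) else 0L)
      }
      d$ext_start[i] <- max(d$basal_start[i] - max_ext, limit_l)
      # neighbours to the right: those whose basal start lies at/after ours
      rs <- d$basal_start[others][d$basal_start[others] >= d$basal_start[i]]
      if (length(rs) && min(rs) <= d$basal_end[i]) {
        limit_r <- d$basal_end[i]
      } else {
        limit_r <- if (length(rs)) min(rs) else Inf
      }
      d$ext_end[i] <- min(d$basal_end[i] + max_ext, limit_r)
    }
  }
  rownames(d) <- NULL
  d
}

#' Intersect top-ranked gene lists with a target set
#'
#' Takes the top `n` entries of two significance-ordered gene lists,
#' intersects them with each other and with `target_set`, and reports the
#' per-source membership (Venn structure) over the union.
#'
#' @param ranked_a,ranked_b Character vectors ordered by significance.
#' @param target_set Character vector (unordered membership set).
#' @param n Number of top entries to take from each ranked list (clipped to
#'   the list length with a warning).
#' @return list with `common` (genes in all three sets), `membership`
#'   (data.frame `gene`, `in_a`, `in_b`, `in_target`) and `venn_counts`
#'   (named vector over the 7 non-empty membership patterns).
#' @export
intersect_top <- function(ranked_a, ranked_b, target_set, n = 200L) {
  take <- function(x, label) {
    if (n > length(x)) {
      warnf("n = %d exceeds length of %s (%d); using the full list",
            n, label, length(x))
      x
    } else {
      utils::head(x, n)
    }
  }
  ta <- take(ranked_a, "ranked_a")
  tb <- take(ranked_b, "ranked_b")
  u <- sort(unique(c(ta, tb, target_set)))
  membership <- data.frame(
    gene = u,
    in_a = u %in% ta,
    in_b = u %in% tb,
    in_target = u %in% target_set,
    stringsAsFactors = FALSE)
  pat <- paste0(ifelse(membership$in_a, "A", ""),
                ifelse(membership$in_b, "B", ""),
                ifelse(membership$in_target, "T", ""))
  venn <- table(factor(pat, levels = c("A", "B", "T", "AB", "AT", "BT", "ABT")))
  list(
    common = membership$gene[membership$in_a & membership$in_b & membership$in_target],
    membership = membership,
    venn_counts = c(venn)
  )
}
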