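#' Per-gene, per-sample percentage of unique insertions
#'
#' For every gene group g and sample s, `D[g, s]` sums the shear-end
#' diversity of the sample's sites in that group (with
#' `denominator = "sites"`, it counts distinct sites instead). Each sample's
#' column is normalized to its total, `P = 100 * D / T`, so columns sum
#' to 100: the screen's "percentage of unique insertions normalized to the
#' total number of insertions in a given sample". Samples with zero total
#' are dropped with a warning.
#'
#' @param annotated Output of [classify_sites()] for all samples (needs
#'   `sample_id`, `group_key`, `diversity`).
#' @param denominator `"diversity"` (default: total summed diversity) or
#'   `"sites"` (count of distinct integration sites).
#' @return Object of class `gene_sample_matrix`: list with `P` (percentage
#'   matrix, genes x samples), `D` (raw matrix), `totals` (per-sample
#'   denominator), `denominator`.
#' @export
percentage_matrix <- function(annotated, denominator = c("diversity", "sites")) {
  denominator <- match.arg(denominator)
  if (nrow(annotated) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(structure(list(P = m, D = m, totals = numeric(0),
                          denominator = denominator),
                     class = "gene_sample_matrix"))
  }
  value <- if (denominator == "diversity") annotated$diversity else
    rep(1L, nrow(annotated))
  D <- tapply(value, list(annotated$group_key, annotated$sample_id), sum,
              default = 0)
  D <- as.matrix(D)
  totals <- colSums(D)
  if (any(totals == 0)) {
    warnf("dropping %d sample(s) with zero total insertions", sum(totals == 0))
    D <- D[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  P <- sweep(D, 2L, totals, "/") * 100
  structure(list(P = P, D = D, totals = totals, denominator = denominator),
            class = "gene_sample_matrix")
}

#' @export
print.gene_sample_matrix <- function(x, ...) {
  cat(sprintf("gene_sample_matrix: %d gene group(s) x %d sample(s), denominator = %s\n",
              nrow(x$P), ncol(x$P), x$denominator))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed from midranks (tied observations get averaged ranks). The
#' p-value is exact -- full enumeration of all `choose(nx + ny, nx)` group
#' labelings -- when both group sizes are at most `exact_max_n` and there
#' are no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used. Two-sided p = min(1, 2 x smaller tail).
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_max_n Largest per-group size for automatic exact enumeration.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) decides by `exact_max_n` and the presence of ties.
#'   Forcing `TRUE` with ties is an error (the enumeration assumes none).
#' @return list with `U` (statistic for `x` relative to `y`),
#'   `p` (two-sided) and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 10L, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) {
    stopf("both groups must be non-empty")
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (length(unique(pooled)) == 1L) {  # fully degenerate: no information
    return(list(U = U, p = 1, method = "degenerate"))
  }

  do_exact <- if (is.null(exact)) {
    nx <= exact_max_n && ny <= exact_max_n && !ties
  } else {
    if (isTRUE(exact) && ties) stopf("exact enumeration requires tie-free data")
    isTRUE(exact)
  }

  if (do_exact) {
    labelings <- utils::combn(N, nx)
    Us <- colSums(matrix(r[labelings], nrow = nx)) - nx * (nx + 1) / 2
    p_one <- min(mean(Us <= U), mean(Us >= U))
    return(list(U = U, p = min(1, 2 * p_one), method = "exact"))
  }

  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(U = U, p = 1, method = "normal"))
  }
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

#' Rank genes enriched in metastatic versus tumour samples
#'
#' For each gene group, the per-sample percentages are split by group and
#' compared with the two-tailed Mann-Whitney U test. Genes are ordered by
#' descending `delta` (mean metastatic minus mean tumour percentage), ties
#' broken by ascending p then gene id. Genes with `delta <= 0` are retained
#' but flagged not-enriched. A Benjamini-Hochberg column is included as
#' supplementary output; the screen's candidate selection uses the raw
#' per-gene p-values.
#'
#' @param mat A [percentage_matrix()] result.
#' @param sample_groups data.frame with `sample_id`, `group` (as from
#'   [sim_samples()]), or a named character vector `sample -> group`.
#' @param case,control Group labels to contrast (case minus control).
#' @param ... Passed to [mann_whitney_u()].
#' @return data.frame with `gene_id`, `mean_pct_met`, `mean_pct_tum`,
#'   `delta`, `U`, `p`, `padj`, `enriched`, ordered as described.
#' @export
rank_enriched <- function(mat, sample_groups, case = "metastatic",
                          control = "tumour", ...) {
  if (is.data.frame(sample_groups)) {
    grp <- stats::setNames(sample_groups$group, sample_groups$sample_id)
  } else {
    grp <- sample_groups
  }
  samples <- colnames(mat$P)
  grp <- grp[samples]
  case_s <- samples[!is.na(grp) & grp == case]
  ctrl_s <- samples[!is.na(grp) & grp == control]
  if (length(case_s) == 0L || length(ctrl_s) == 0L) {
    stopf("configuration error: need at least one sample in each of '%s' and '%s'",
          case, control)
  }
  genes <- rownames(mat$P)
  res <- lapply(genes, function(g) {
    xs <- mat$P[g, case_s]
    ys <- mat$P[g, ctrl_s]
    mw <- mann_whitney_u(xs, ys, ...)
    data.frame(gene_id = g, mean_pct_met = mean(xs), mean_pct_tum = mean(ys),
               delta = mean(xs) - mean(ys), U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$delta > 0
  res <- res[order(-res$delta, res$p, res$gene_id), ]
  rownames(res) <- NULL
  res
}
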