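# Percentage matrix, Mann-Whitney U, and enrichment ranking.

test_that("percentages are diversity sums over the per-sample total, x100", {
  ann <- data.frame(
    sample_id = "s1",
    group_key = c("gA", "gA", "gB", "gC"),
    diversity = c(3L, 1L, 30L, 6L),
    stringsAsFactors = FALSE)
  m <- percentage_matrix(ann)
  expect_equal(m$P["gA", "s1"], 10)  # 4 of 40
  expect_equal(unname(colSums(m$P)), 100)
  ms <- percentage_matrix(ann, denominator = "sites")
  expect_equal(ms$P["gA", "s1"], 50)  # 2 of 4 sites
})

test_that("column sums are 100 for every simulated sample and D re-aggregates", {
  cfg <- sim_config(seed = 351, n_chroms = 1, chrom_length = 3e5, n_genes = 10,
                    groups = c(tumour = 3, metastatic = 3), n_insertions = 40)
  res <- truth_ranking(cfg)
  expect_equal(unname(colSums(res$matrix$P)),
               rep(100, ncol(res$matrix$P)))
  # independent re-aggregation from BED files
  beds <- tempfile()
  dir.create(beds)
  for (sid in unique(res$annotated$sample_id)) {
    a <- res$annotated[res$annotated$sample_id == sid, ]
    s <- data.frame(sample_id = a$sample_id, chrom = a$chrom,
                    strand = a$strand, coord = a$coord, upstream4 = "TTAA",
                    diversity = a$diversity, raw_reads = a$diversity,
                    stringsAsFactors = FALSE)
    write_sites_bed(s, file.path(beds, paste0(sid, ".bed")))
  }
  for (sid in colnames(res$matrix$D)) {
    back <- read_sites_bed(file.path(beds, paste0(sid, ".bed")))
    key <- paste(back$chrom, back$strand, back$coord)
    ann_s <- res$annotated[res$annotated$sample_id == sid, ]
    gk <- setNames(ann_s$group_key, paste(ann_s$chrom, ann_s$strand, ann_s$coord))
    resum <- tapply(back$diversity, gk[key], sum)
    expect_equal(resum[rownames(res$matrix$D)[res$matrix$D[, sid] > 0]],
                 res$matrix$D[res$matrix$D[, sid] > 0, sid],
                 ignore_attr = TRUE)
  }
})

test_that("scaling one sample's diversities leaves its percentage column fixed", {
  ann <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    group_key = rep(c("gA", "gB", "gC"), 2),
    diversity = c(2L, 5L, 3L, 4L, 4L, 2L),
    stringsAsFactors = FALSE)
  base <- percentage_matrix(ann)
  ann$diversity[ann$sample_id == "s1"] <- ann$diversity[ann$sample_id == "s1"] * 7L
  scaled <- percentage_matrix(ann)
  expect_equal(scaled$P, base$P)
})

test_that("Mann-Whitney U matches hand-derived and enumerated references", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 * 1/20 labelings
  expect_identical(mw$method, "exact")

  same <- mann_whitney_u(c(2, 9, 4), c(9, 2, 4))
  expect_identical(same$U, 4.5)
  expect_equal(same$p, 1)

  deg <- mann_whitney_u(rep(3, 4), rep(3, 5))
  expect_identical(deg$U, 10)  # n_x n_y / 2
  expect_equal(deg$p, 1)
})

test_that("exact p agrees with stats::wilcox.test on tie-free data", {
  set.seed(352)
  for (rep in 1:20) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- round(rnorm(nx), 6); y <- round(rnorm(ny), 6)
    mw <- mann_whitney_u(x, y)
    w <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(mw$U, unname(w$statistic))
    expect_equal(mw$p, w$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation is close to exact for n = 8 + 8", {
  set.seed(353)
  gaps <- replicate(50, {
    x <- rnorm(8); y <- rnorm(8)
    abs(mann_whitney_u(x, y, exact = TRUE)$p -
          mann_whitney_u(x, y, exact = FALSE)$p)
  })
  expect_lt(median(gaps), 0.01)
  expect_lt(max(gaps), 0.015)  # residual discreteness at n = 8 + 8
})

test_that("tie-corrected approximation matches wilcox.test's on tied data", {
  set.seed(354)
  for (rep in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 14, replace = TRUE)
    mw <- mann_whitney_u(x, y)
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mw$p, w$p.value, tolerance = 1e-9)
  }
})

test_that("ranking orders by delta, flags non-enriched, and needs both groups", {
  P <- rbind(gA = c(10, 12, 30, 33),
             gB = c(50, 48, 40, 37),
             gC = c(40, 40, 30, 30))
  colnames(P) <- c("t1", "t2", "m1", "m2")
  mat <- structure(list(P = P, D = P, totals = rep(100, 4),
                        denominator = "diversity"),
                   class = "gene_sample_matrix")
  groups <- data.frame(sample_id = colnames(P),
                       group = c("tumour", "tumour", "metastatic", "metastatic"))
  r <- rank_enriched(mat, groups)
  expect_identical(r$gene_id, c("gA", "gC", "gB"))
  expect_equal(r$delta, c(20.5, -10, -10.5))
  expect_identical(r$enriched, c(TRUE, FALSE, FALSE))
  expect_error(rank_enriched(mat, data.frame(sample_id = colnames(P),
                                             group = "tumour")),
               "at least one sample")
})

test_that("swapping group labels negates delta and preserves p", {
  set.seed(355)
  P <- matrix(runif(40, 0, 20), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  mat <- structure(list(P = P, D = P, totals = rep(1, 8),
                        denominator = "diversity"),
                   class = "gene_sample_matrix")
  g1 <- data.frame(sample_id = colnames(P),
                   group = rep(c("tumour", "metastatic"), each = 4))
  g2 <- data.frame(sample_id = colnames(P),
                   group = rep(c("metastatic", "tumour"), each = 4))
  r1 <- rank_enriched(mat, g1)
  r2 <- rank_enriched(mat, g2)
  r2 <- r2[match(r1$gene_id, r2$gene_id), ]
  expect_equal(r1$delta, -r2$delta)
  expect_equal(r1$p, r2$p)
})
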