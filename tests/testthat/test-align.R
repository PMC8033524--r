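# Built-in unique-pair aligner and SAM interchange.

set.seed(321)
toy_genome <- Biostrings::DNAStringSet(c(chr1 = paste(
  sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")))
toy_seq <- as.character(toy_genome[[1]])

test_that("a pair from a unique locus aligns at the exact junction", {
  c0 <- 2000L; L <- 260L
  pairs <- data.frame(
    id = "p1",
    read1 = substr(toy_seq, c0 + 1, c0 + 91),
    read2 = revcomp(substr(toy_seq, c0 + L - 99, c0 + L)),
    stringsAsFactors = FALSE)
  res <- align_pairs(pairs, toy_genome)
  expect_identical(nrow(res$pairs), 1L)
  expect_identical(res$pairs$strand, "+")
  expect_identical(res$pairs$r1_start, c0)
  expect_identical(res$pairs$shear_end, c0 + L)
  expect_identical(res$pairs$insert_size, L)

  # minus-strand pair: junction at c0, fragment extends left
  pairs_m <- data.frame(
    id = "m1",
    read1 = revcomp(substr(toy_seq, c0 - 91 + 1, c0)),
    read2 = substr(toy_seq, c0 - L + 1, c0 - L + 100),
    stringsAsFactors = FALSE)
  res_m <- align_pairs(pairs_m, toy_genome)
  expect_identical(res_m$pairs$strand, "-")
  expect_identical(res_m$pairs$r1_start, c0)
  expect_identical(res_m$pairs$shear_end, c0 - L)
})

test_that("one mismatch outside the seed is tolerated; two are not", {
  c0 <- 3000L
  r1 <- substr(toy_seq, c0 + 1, c0 + 91)
  flip <- function(s, i) {
    b <- substr(s, i, i)
    paste0(substr(s, 1, i - 1), setdiff(c("A", "C", "G", "T"), b)[1],
           substr(s, i + 1, nchar(s)))
  }
  r2 <- revcomp(substr(toy_seq, c0 + 161, c0 + 260))
  one <- align_pairs(data.frame(id = "x", read1 = flip(r1, 50), read2 = r2,
                                stringsAsFactors = FALSE), toy_genome)
  expect_identical(one$pairs$r1_start, c0)
  two <- align_pairs(data.frame(id = "x", read1 = flip(flip(r1, 50), 70),
                                read2 = r2, stringsAsFactors = FALSE), toy_genome)
  expect_identical(nrow(two$pairs), 0L)
  expect_identical(two$stats$unmapped, 1L)
})

test_that("reads from a duplicated locus are rejected as multi-mappers", {
  dup <- substr(toy_seq, 1001, 1400)
  genome2 <- Biostrings::DNAStringSet(c(
    chr1 = toy_seq,
    chr2 = paste0(substr(toy_seq, 4001, 5600), dup,
                  substr(toy_seq, 5601, 6000))))
  pairs <- data.frame(
    id = "d1",
    read1 = substr(dup, 1, 91),
    read2 = revcomp(substr(dup, 201, 300)),
    stringsAsFactors = FALSE)
  res <- align_pairs(pairs, genome2)
  expect_identical(nrow(res$pairs), 0L)
  expect_identical(res$stats$multimapped, 1L)
})

test_that("mates farther than the insert cap are excluded", {
  c0 <- 1500L
  pairs <- data.frame(
    id = "far",
    read1 = substr(toy_seq, c0 + 1, c0 + 91),
    read2 = revcomp(substr(toy_seq, c0 + 1401, c0 + 1500)),
    stringsAsFactors = FALSE)
  res <- align_pairs(pairs, toy_genome, max_insert = 1000L)
  expect_identical(nrow(res$pairs), 0L)
  expect_identical(res$stats$mate_failed, 1L)
})

test_that("with zero noise every emitted pair (duplicates included) is reported", {
  cfg <- sim_config(seed = 322, n_chroms = 1, chrom_length = 2e5, n_genes = 6,
                    groups = c(tumour = 1, metastatic = 1), n_insertions = 15,
                    pcr_dup_mean = 2, seq_error_rate = 0, contaminant_frac = 0)
  ref <- gen_reference(cfg)
  truth <- plant_insertions(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  for (sid in names(sim$reads)) {
    trimmed <- trim_prefix(sim$reads[[sid]])
    res <- align_pairs(trimmed$pairs, ref$genome)
    expect_identical(res$stats$reported, nrow(sim$reads[[sid]]))
  }
})

test_that("SAM round-trip reproduces the aligned-pair set", {
  cfg <- sim_config(seed = 323, n_chroms = 1, chrom_length = 2e5, n_genes = 6,
                    groups = c(tumour = 1, metastatic = 1), n_insertions = 10,
                    pcr_dup_mean = 1, seq_error_rate = 0, contaminant_frac = 0)
  ref <- gen_reference(cfg)
  truth <- plant_insertions(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  trimmed <- trim_prefix(sim$reads[[1]])
  res <- align_pairs(trimmed$pairs, ref$genome)
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(res$pairs, ref$genome, sam)
  back <- read_alignments(sam)
  cols <- c("chrom", "strand", "r1_start", "shear_end", "insert_size")
  a <- res$pairs[order(res$pairs$id), cols]
  b <- back$pairs[order(back$pairs$id), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("SAM conversion is 1-based at the boundary and skips secondary records", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    "p1\t99\tchr1\t101\t60\t50M\t=\t301\t250\t*\t*",
    "p1\t147\tchr1\t301\t60\t50M\t=\t101\t-250\t*\t*",
    "p2\t355\tchr1\t501\t60\t50M\t=\t701\t250\t*\t*",   # secondary
    "p2\t403\tchr1\t701\t60\t50M\t=\t501\t-250\t*\t*"), # secondary
    sam)
  res <- read_alignments(sam)
  expect_identical(nrow(res$pairs), 1L)
  expect_identical(res$pairs$r1_start, 100L)   # POS 101 -> 0-based 100
  expect_identical(res$pairs$shear_end, 350L)  # mate end = 300 + 50
})
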