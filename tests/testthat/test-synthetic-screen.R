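# Generator: determinism, genome/annotation structure, planted-truth
# properties, and read-level library composition.

small_cfg <- sim_config(seed = 301, n_chroms = 1, chrom_length = 2e5,
                        n_genes = 8, groups = c(tumour = 2, metastatic = 2),
                        n_insertions = 20, pcr_dup_mean = 1,
                        seq_error_rate = 0, contaminant_frac = 0)
small_ref <- gen_reference(small_cfg)
small_truth <- plant_insertions(small_ref, small_cfg)

test_that("identical configs reproduce byte-identical FASTA, GTF and reads", {
  cfg <- small_cfg
  out1 <- file.path(tempdir(), "det1")
  out2 <- file.path(tempdir(), "det2")
  dir.create(out1, showWarnings = FALSE)
  dir.create(out2, showWarnings = FALSE)
  for (out in c(out1, out2)) {
    ref <- gen_reference(cfg)
    write_reference(ref, file.path(out, "g.fa"), file.path(out, "t.gtf"))
    truth <- plant_insertions(ref, cfg)
    sim <- simulate_reads(ref, truth, cfg, outdir = out)
  }
  for (f in c("g.fa", "t.gtf")) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }
  fq <- list.files(out1, pattern = "fastq.gz$")
  expect_gt(length(fq), 0)
  for (f in fq) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }
})

test_that("TTAA content matches a naive sliding-window scan", {
  cfg <- sim_config(seed = 302, n_chroms = 1, chrom_length = 5e4, n_genes = 5)
  ref <- gen_reference(cfg)
  seq <- as.character(ref$genome[[1]])
  expected <- oracle_ttaa_count(seq)
  expect_identical(Biostrings::vcountPattern("TTAA", ref$genome)[1], expected)
  tt <- ttaa_positions(ref$genome)
  expect_identical(nrow(tt), expected)
  expect_true(all(substr(seq, tt$pos + 1, tt$pos + 4) == "TTAA"))
})

test_that("transcript models are structurally valid and inside chromosomes", {
  tx <- small_ref$transcripts
  len <- length(small_ref$genome[[1]])
  expect_true(all(tx$tx_start >= 0 & tx$tx_end <= len))
  expect_true(all(tx$tx_start < tx$tx_end))
  for (i in seq_len(nrow(tx))) {
    ex <- exon_matrix(tx[i, ])
    expect_true(all(diff(as.vector(t(ex))) >= 0))     # sorted, non-overlapping
    expect_identical(unname(ex[1, 1]), tx$tx_start[i])
    expect_identical(unname(ex[nrow(ex), 2]), tx$tx_end[i])
    if (!is.na(tx$cds_start[i])) {
      expect_true(tx$cds_start[i] < tx$cds_end[i])
      expect_true(any(ex[, 1] <= tx$cds_start[i] & tx$cds_start[i] < ex[, 2]))
      expect_true(any(ex[, 1] < tx$cds_end[i] & tx$cds_end[i] <= ex[, 2]))
    }
  }
  expect_true(any(is.na(tx$cds_start)))  # some genes are non-coding
})

test_that("GTF round-trip preserves the transcript table", {
  gtf <- tempfile(fileext = ".gtf")
  rtracklayer::export(pbscreen:::transcripts_to_granges(small_ref$transcripts),
                      gtf, format = "gtf")
  back <- read_transcripts_gtf(gtf)
  orig <- small_ref$transcripts[order(small_ref$transcripts$chrom,
                                      small_ref$transcripts$tx_start,
                                      small_ref$transcripts$transcript_id), ]
  rownames(orig) <- NULL
  expect_equal(back[, names(orig)], orig)
})

test_that("every planted coordinate sits immediately 3' of a TTAA on its strand", {
  g <- as.character(small_ref$genome[[1]])
  plus <- small_truth$strand == "+"
  up <- character(nrow(small_truth))
  up[plus] <- substr(g, small_truth$coord[plus] - 3, small_truth$coord[plus])
  up[!plus] <- revcomp(substr(g, small_truth$coord[!plus] + 1,
                              small_truth$coord[!plus] + 4))
  expect_true(all(up == "TTAA"))
  expect_true(all(small_truth$true_diversity >= 1))
})

test_that("fold 1 plants no extra insertions (null design)", {
  cfg <- small_cfg
  cfg$enriched_genes <- data.frame(gene_id = c("g002", "g005"),
                                   group = "metastatic", fold = 1)
  truth <- plant_insertions(small_ref, cfg)
  counts <- table(truth$sample_id)
  # collisions can merge a few sites, so counts can only be <= the target
  expect_true(all(counts <= cfg$n_insertions))
  expect_true(all(counts >= cfg$n_insertions - 3))
})

test_that("planted fold elevation raises the gene's diversity in the named group", {
  base <- sim_config(seed = 303, n_chroms = 1, chrom_length = 5e5, n_genes = 12,
                     groups = c(tumour = 6, metastatic = 6), n_insertions = 60,
                     enriched_genes = data.frame(gene_id = "g006",
                                                 group = "metastatic", fold = 5))
  ref <- gen_reference(base)
  samples <- sim_samples(base)
  wins <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    cfg <- base
    cfg$seed <- 9000L + s
    truth <- plant_insertions(ref, cfg)
    in_gene <- truth[!is.na(truth$gene_id) & truth$gene_id == "g006", ]
    by_sample <- tapply(in_gene$true_diversity, in_gene$sample_id, sum)
    div <- setNames(rep(0, nrow(samples)), samples$sample_id)
    div[names(by_sample)] <- by_sample
    met <- mean(div[samples$sample_id[samples$group == "metastatic"]])
    tum <- mean(div[samples$sample_id[samples$group == "tumour"]])
    wins <- wins + (met > tum)
  }
  expect_gte(wins, ceiling(0.95 * n_seeds))
})

test_that("no-noise library conserves fragments and prefixes every read 1", {
  sim <- simulate_reads(small_ref, small_truth, small_cfg)
  cfg0 <- small_cfg
  cfg0$pcr_dup_mean <- 0
  sim0 <- simulate_reads(small_ref, small_truth, cfg0)
  for (sid in names(sim0$reads)) {
    expect_identical(nrow(sim0$reads[[sid]]),
                     sum(small_truth$true_diversity[small_truth$sample_id == sid]))
  }
  all_r1 <- unlist(lapply(sim$reads, function(d) d$read1))
  expect_true(all(startsWith(all_r1, "TAGGGTTAA")))
})

test_that("contaminant fraction matches its nominal rate within binomial error", {
  cfg <- sim_config(seed = 304, n_chroms = 1, chrom_length = 3e5, n_genes = 8,
                    groups = c(tumour = 2, metastatic = 2), n_insertions = 80,
                    pcr_dup_mean = 4, seq_error_rate = 0, contaminant_frac = 0.01)
  ref <- gen_reference(cfg)
  truth <- plant_insertions(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg)
  r1 <- unlist(lapply(sim$reads, function(d) d$read1))
  frac <- mean(!startsWith(r1, "TAGGGTTAA"))
  n <- length(r1)
  se <- sqrt(0.01 * 0.99 / n)
  expect_gt(n, 2000)
  expect_lt(abs(frac - 0.01), 4 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(seq_error_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(chrom_length = 1000), "10 x fragment_length_mean")
  expect_error(sim_config(chrom_length = 30000, n_genes = 50),
               "too small to host")
  expect_error(sim_config(enriched_genes = data.frame(
    gene_id = "g001", group = "nosuch", fold = 2)), "unknown group")
})
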