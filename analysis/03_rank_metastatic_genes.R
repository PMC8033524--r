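#!/usr/bin/env Rscript
# Annotate integration sites against the gene hierarchy, build the
# per-sample percentage-of-unique-insertions matrix, rank genes enriched in
# metastatic versus tumour samples, and score recovery against the planted
# truth.

suppressPackageStartupMessages(library(pbscreen))

indir <- "scratch/screen"
samples <- read.delim(file.path(indir, "samples.tsv"))
transcripts <- read_transcripts_gtf(file.path(indir, "transcripts.gtf"))
truth <- read.delim(file.path(indir, "truth.tsv"))

sites <- do.call(rbind, lapply(samples$sample_id, function(sid) {
  read_sites_bed(file.path("results/sites", paste0(sid, ".bed")), sample_id = sid)
}))

rec <- evaluate_recovery(sites, truth)
cat(sprintf("recovery: %d/%d planted sites (%.1f%%), %d spurious (diversity>=2: %d)\n",
            rec$n_recovered, rec$n_truth, 100 * rec$recovery, rec$spurious,
            rec$spurious_high_diversity))

annotated <- classify_sites(sites, transcripts)
cat("\nsite categories:\n")
print(table(annotated$category))

mat <- percentage_matrix(annotated)
ranking <- rank_enriched(mat, samples)
write.table(ranking, "results/03_enrichment_ranking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(category = names(table(annotated$category)),
                       n_sites = as.integer(table(annotated$category))),
            "results/03_category_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

genes_only <- ranking[grepl("^g[0-9]+$", ranking$gene_id), ]
cat("\ntop 5 candidate metastasis genes (by delta of % unique insertions):\n")
print(head(genes_only[, c("gene_id", "mean_pct_met", "mean_pct_tum",
                          "delta", "U", "p")], 5), digits = 3)
cat("outputs: results/03_enrichment_ranking.tsv, results/03_category_counts.tsv\n")
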