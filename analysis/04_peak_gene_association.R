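#!/usr/bin/env Rscript
# Basal+extension association of (simulated) ChIP peaks with genes, and the
# intersection of two significance-ranked expression lists with the
# associated target set -- the route by which a screen hit's downstream
# effector is pinned.

suppressPackageStartupMessages(library(pbscreen))

transcripts <- read_transcripts_gtf("scratch/screen/transcripts.gtf")

set.seed(4)
# peaks: two planted near g025's promoter and a handful of decoys
dom <- great_domains(transcripts)
target <- dom[dom$gene_id == "g025", ]
peaks <- rbind(
  data.frame(chrom = target$chrom, start = target$tss - 3500,
             end = target$tss - 3100, peak_id = "peak_near_1"),
  data.frame(chrom = target$chrom, start = target$tss - 9000,
             end = target$tss - 8600, peak_id = "peak_near_2"),
  data.frame(chrom = "chr1", start = sample(seq(2e4, 9.5e5, by = 1000), 6),
             end = NA, peak_id = paste0("decoy_", 1:6)))
peaks$end[is.na(peaks$end)] <- peaks$start[is.na(peaks$end)] + 400

assoc <- great_associate(peaks, transcripts,
                         basal_up = 5000, basal_down = 1000, max_ext = 10000)
write.table(assoc$assoc, "results/04_peak_gene_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("peak-to-gene associations (basal 5 kb up / 1 kb down, 10 kb max extension):\n")
print(assoc$assoc)

# two ranked "differential expression" lists sharing one associated target
chip_targets <- unique(assoc$assoc$gene_id)
list_a <- c("g025", paste0("x", 1:199))        # e.g. tumoursphere ranking
list_b <- c("y1", "g025", paste0("y", 2:199))  # e.g. tumour ranking
common <- intersect_top(list_a, list_b, chip_targets, n = 200)
cat(sprintf("\nsingle common gene across both top-200 lists and the target set: %s\n",
            paste(common$common, collapse = ", ")))
print(common$venn_counts)
cat("outputs: results/04_peak_gene_map.tsv\n")
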