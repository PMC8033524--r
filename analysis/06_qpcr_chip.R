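#!/usr/bin/env Rscript
# Relative expression (2^-ddCt, technical duplicates averaged) and
# ChIP-qPCR percent-input for a promoter region versus an IgG control.

suppressPackageStartupMessages(library(pbscreen))
dir.create("results", showWarnings = FALSE)

# expression of a target gene in knockdown vs control lines,
# normalized to a housekeeping gene (Ct technical duplicates)
qpcr <- rbind(
  data.frame(line = "control",   ct_target = c(24.1, 24.3), ct_hk = c(18.2, 18.1)),
  data.frame(line = "knockdown", ct_target = c(27.0, 27.2), ct_hk = c(18.3, 18.2)),
  data.frame(line = "overexpr",  ct_target = c(22.4, 22.5), ct_hk = c(18.1, 18.2)))
ctrl <- qpcr[qpcr$line == "control", ]
fc <- vapply(unique(qpcr$line), function(l) {
  s <- qpcr[qpcr$line == l, ]
  ddct_fold_change(s$ct_target, s$ct_hk, ctrl$ct_target, ctrl$ct_hk)
}, numeric(1))
fold <- data.frame(line = names(fc), fold_change = round(fc, 3))
write.table(fold, "results/06_qpcr_fold_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("2^-ddCt fold changes vs control:\n")
print(fold, row.names = FALSE)

# ChIP-qPCR at two promoter amplicons, 1% input chromatin
chip <- data.frame(
  antibody = c("target_TF", "target_TF", "IgG", "IgG"),
  amplicon = c("promoter_peak1", "promoter_peak2", "promoter_peak1",
               "promoter_peak2"),
  ct_ip = c(26.8, 27.5, 31.9, 32.3),
  ct_input = c(25.0, 25.4, 25.0, 25.4))
chip$percent_input <- round(
  mapply(percent_input, chip$ct_ip, chip$ct_input,
         MoreArgs = list(input_fraction = 0.01)), 3)
write.table(chip, "results/06_chip_percent_input.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nChIP-qPCR percent input (1% input):\n")
print(chip, row.names = FALSE)
cat("outputs: results/06_qpcr_fold_changes.tsv, results/06_chip_percent_input.tsv\n")
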