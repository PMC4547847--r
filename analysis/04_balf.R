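#!/usr/bin/env Rscript
# BALF compartment analysis: SAM-style BALF-vs-tissue enrichment scores
# (ELF classification), the day-14 differential t-test, and the one-way
# ANOVA of BALF ratios over time.

library(qdspr)

simdir <- "results/simulated"
out <- "results"
tab <- read_protein_groups(file.path(simdir, "balf_proteinGroups.txt"),
                           file.path(simdir, "balf_samples.tsv"))
truth <- read.delim(file.path(simdir, "balf_truth.tsv"), comment.char = "#")
stopifnot(nrow(validate_design(tab$samples, "BALF")) == 0)

lm2 <- log2_matrix(tab)
is_balf <- tab$samples$compartment == "BALF"
sc <- sam_scores(lm2[, is_balf, drop = FALSE], lm2[, !is_balf, drop = FALSE],
                 sam_params(seed = 21L), fdr = 0.05)
write_result_table(sc, file.path(out, "balf_scores.tsv"),
                   meta = list(seed = 21, s0 = sc$s0[1]))
cat(sprintf(paste0(
  "SAM scores (s0 = %.3f, 5th percentile of the scatter): %d ELF-enriched ",
  "at FDR 0.05\n  vs truth: sensitivity %.2f, empirical FDR %.2f\n"),
  sc$s0[1], sum(sc$elf_enriched),
  mean(sc$elf_enriched[truth$elf_member]),
  sum(sc$elf_enriched & !truth$elf_member) / max(1, sum(sc$elf_enriched))))

d14 <- balf_day14_ttest(tab)
write_result_table(d14, file.path(out, "balf_day14.tsv"), meta = list())
bt <- balf_timecourse(tab, imputation_params(seed = 22L))
write_result_table(bt$anova, file.path(out, "balf_anova.tsv"),
                   meta = list(seed = 22))
cat(sprintf(paste0(
  "Day-14 t-test: %d significant; BALF time-course ANOVA: %d significant ",
  "(FDR 0.05)\n"),
  sum(d14$q < 0.05, na.rm = TRUE), sum(bt$anova$q < 0.05, na.rm = TRUE)))
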