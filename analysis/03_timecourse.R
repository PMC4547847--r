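#!/usr/bin/env Rscript
# Tissue time course: per-replicate log2 ratios against the PBS median with
# the validity/imputation rules, one-way ANOVA over time, and per-protein
# regression of abundance on lung compliance.

library(qdspr)

simdir <- "results/simulated"
out <- "results"
tab <- read_protein_groups(file.path(simdir, "timecourse_proteinGroups.txt"),
                           file.path(simdir, "timecourse_samples.tsv"))
truth <- read.delim(file.path(simdir, "timecourse_truth.tsv"),
                    comment.char = "#")
mice <- read.delim(file.path(simdir, "timecourse_mice.tsv"),
                   comment.char = "#")
stopifnot(nrow(validate_design(tab$samples, "TIMECOURSE")) == 0)

ratios <- compute_ratios(tab, imputation_params(seed = 11L))
prov <- table(factor(ratios$provenance, qdspr:::RATIO_PROVENANCE))
cat(sprintf("Ratios: %d proteins x %d treated mice; provenance %s\n",
            nrow(ratios$log2_ratio), ncol(ratios$log2_ratio),
            paste(sprintf("%s=%d", names(prov), prov), collapse = ", ")))
rt <- data.frame(protein_id = rownames(ratios$log2_ratio),
                 ratios$log2_ratio, check.names = FALSE)
write_result_table(rt, file.path(out, "timecourse_ratios.tsv"),
                   meta = list(seed = 11))

an <- anova_timecourse(ratios)
write_result_table(an, file.path(out, "timecourse_anova.tsv"),
                   meta = list(seed = 11))
det <- !is.na(an$q) & an$q < 0.05
maxfc <- apply(abs(as.matrix(truth[, grep("true_log2fc_", names(truth))])),
               1, max)
cat(sprintf(paste0(
  "ANOVA over time: %d significant at FDR 0.05; sensitivity %.2f for true ",
  "|log2fc| >= 1, empirical FDR %.2f\n"),
  sum(det), mean(det[maxfc >= 1]),
  sum(det & !truth$changed) / max(1, sum(det))))

comp <- compliance_regression(
  ratios, control_compliance = mice$compliance[mice$condition == "PBS"])
write_result_table(comp, file.path(out, "compliance.tsv"),
                   meta = list(seed = 11))
detc <- !is.na(comp$q) & comp$q < 0.05
fib <- !is.na(truth$archetype) & truth$archetype == "FIBROTIC"
cat(sprintf(paste0(
  "Compliance regression: %d significant correlations; %d are ",
  "fibrotic-archetype proteins, of which %.0f%% have negative slope\n",
  "  (they accumulate as the lung stiffens, the Tnc-like direction)\n"),
  sum(detc), sum(detc & fib), 100 * mean(comp$slope[detc & fib] < 0)))
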