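#!/usr/bin/env Rscript
# Simulate the three study designs (QDSP, tissue time course, BALF) with
# known ground truth and write them in the proteinGroups dialect, so the
# downstream steps exercise the same readers a real dataset would.

library(qdspr)

seed <- 1L
n_proteins <- 2000L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_proteins = n_proteins, seed = seed)

qdsp <- generate_qdsp_dataset(cfg)
write_protein_groups(qdsp$table, file.path(out, "qdsp_proteinGroups.txt"),
                     file.path(out, "qdsp_samples.tsv"))
write_result_table(qdsp$truth, file.path(out, "qdsp_truth.tsv"),
                   meta = list(seed = seed))

tc <- generate_timecourse_dataset(cfg)
write_protein_groups(tc$table, file.path(out, "timecourse_proteinGroups.txt"),
                     file.path(out, "timecourse_samples.tsv"))
write_result_table(tc$truth, file.path(out, "timecourse_truth.tsv"),
                   meta = list(seed = seed))
write_result_table(tc$mice, file.path(out, "timecourse_mice.tsv"),
                   meta = list(seed = seed))

balf <- generate_balf_dataset(cfg)
write_protein_groups(balf$table, file.path(out, "balf_proteinGroups.txt"),
                     file.path(out, "balf_samples.tsv"))
write_result_table(balf$truth, file.path(out, "balf_truth.tsv"),
                   meta = list(seed = seed))

ann <- generate_annotations(qdsp$truth, noise_frac = 0.1, seed = seed + 13L)
write_gmt(ann, file.path(out, "annotations.gmt"))

cat(sprintf(paste0(
  "Simulated %d proteins per design (seed %d):\n",
  "  QDSP: %d samples, %.1f%% missing, %d profile-shifted proteins\n",
  "  time course: %d mice (%d PBS), %d changed proteins\n",
  "  BALF: %d samples, %d ELF members\n"),
  n_proteins, seed,
  ncol(qdsp$table$values), 100 * mean(is.na(qdsp$table$values)),
  sum(qdsp$truth$profile_shifted),
  nrow(tc$mice), sum(tc$mice$condition == "PBS"), sum(tc$truth$changed),
  ncol(balf$table$values), sum(balf$truth$elf_member)))
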