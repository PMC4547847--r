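#!/usr/bin/env Rscript
# QDSP analysis: read the simulated proteinGroups table back from disk, test
# solubility-profile changes (treatment x fraction interaction ANOVA),
# summarize insoluble shares, and characterize fraction structure by PCA and
# correlation clustering.

library(qdspr)

simdir <- "results/simulated"
out <- "results"
tab <- read_protein_groups(file.path(simdir, "qdsp_proteinGroups.txt"),
                           file.path(simdir, "qdsp_samples.tsv"))
truth <- read.delim(file.path(simdir, "qdsp_truth.tsv"), comment.char = "#")

stopifnot(nrow(validate_design(tab$samples, "QDSP")) == 0)
st <- qdsp_stats(tab, fdr = 0.05)
write_result_table(st, file.path(out, "qdsp_stats.tsv"),
                   meta = list(input = "qdsp_proteinGroups.txt"))

hits <- st$significant_profile
cat(sprintf(paste0(
  "Interaction ANOVA: %d/%d proteins tested, %d significant at FDR 0.05\n",
  "  recovery vs ground truth: sensitivity %.2f, empirical FDR %.2f\n",
  "  insoluble share rises for %.0f%% of detected toward-insoluble shifts\n"),
  sum(st$interaction_tested), nrow(st), sum(hits),
  mean(hits[truth$profile_shifted]),
  sum(hits & !truth$profile_shifted) / max(1, sum(hits)),
  100 * mean(st$delta_insoluble_share[
    hits & truth$profile_shifted &
      truth$shift_direction == "TOWARD_INSOLUBLE"] > 0, na.rm = TRUE)))

# PCA of fraction samples over complete-case z-scored proteins
lm2 <- log2_matrix(tab)
complete <- rowSums(is.na(lm2)) == 0
z <- zscore_rows(lm2[complete, , drop = FALSE])
pc <- pca_fractions(t(z), n_components = 4)
scores <- data.frame(sample_id = tab$samples$sample_id,
                     fraction = tab$samples$fraction,
                     condition = tab$samples$condition, pc$scores)
write_result_table(scores, file.path(out, "qdsp_pca_scores.tsv"),
                   meta = list(n_proteins = sum(complete)))
write_result_table(data.frame(protein_id = rownames(z), pc$loadings),
                   file.path(out, "qdsp_pca_loadings.tsv"),
                   meta = list(n_proteins = sum(complete)))
sep <- tapply(scores$PC1, scores$fraction, mean)
cat(sprintf("PCA: PC1 %.0f%% / PC2 %.0f%% of variance; PC1 separates FR1 (%.1f) from INSOL (%.1f)\n",
            100 * pc$variance_explained[1], 100 * pc$variance_explained[2],
            sep["FR1"], sep["INSOL"]))

# correlation-distance clustering of the significant profiles
sig_idx <- which(hits & complete[match(st$protein_id, rownames(lm2))])
if (length(sig_idx) >= 2) {
  cl <- cluster_profiles(z[rownames(z) %in% st$protein_id[sig_idx], ,
                           drop = FALSE], k = 2)
  cat(sprintf("Clustering: %d significant complete profiles in 2 clusters (sizes %s)\n",
              length(cl$clusters), paste(table(cl$clusters), collapse = "/")))
}
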