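AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Count theoretically observable tryptic peptides
#'
#' Fully cleaved in-silico trypsin digest: cleavage C-terminal of K or R,
#' suppressed when the next residue is P, no missed cleavages. Peptides with
#' length in `[min_len, max_len]` are counted; this is the iBAQ denominator.
#'
#' @param sequence amino-acid string (standard 20-letter alphabet).
#' @param min_len,max_len inclusive peptide length bounds (defaults 7 and 30,
#'   the usual observable range for shotgun MS).
#' @return integer count of in-range peptides.
#' @export
count_tryptic_peptides <- function(sequence, min_len = 7L, max_len = 30L) {
  stopifnot(length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) {
    warning("empty sequence: 0 theoretical peptides")
    return(0L)
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% AA_LETTERS))
    stop("illegal amino-acid character(s): ",
         paste(unique(aa[!aa %in% AA_LETTERS]), collapse = ", "))
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after[cut_after < n], n)
  lens <- diff(bounds)
  sum(lens >= min_len & lens <= max_len)
}

#' iBAQ: intensity normalized by theoretical peptide count
#'
#' @param intensity positive linear intensity (vectorized).
#' @param n_theoretical_peptides positive integer count (vectorized).
#' @return `intensity / n_theoretical_peptides`; `NA` with a warning where the
#'   peptide count is 0.
#' @export
compute_ibaq <- function(intensity, n_theoretical_peptides) {
  out <- intensity / n_theoretical_peptides
  zero <- !is.na(n_theoretical_peptides) & n_theoretical_peptides == 0
  if (any(zero)) {
    warning(sum(zero), " protein(s) with 0 theoretical peptides: iBAQ set NA")
    out[zero] <- NA_real_
  }
  out
}

#' Relative stoichiometry of a protein family
#'
#' Normalizes a vector of iBAQ values to sum 1 over the family (e.g. laminin
#' chains); `NA` members are excluded and the remainder renormalized.
#'
#' @param ibaq named numeric vector of iBAQ values for the family.
#' @return named numeric vector summing to 1 over non-`NA` members.
#' @export
ibaq_stoichiometry <- function(ibaq) {
  tot <- sum(ibaq, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("no positive iBAQ values in family")
  ibaq / tot
}

#' Match proteome and transcriptome ratios
#'
#' Intersects per-gene protein and RNA log2 ratios, keeps genes whose
#' transcript passes the expression cutoff (log2 FPKM >= `fpkm_log2_cutoff`),
#' and reports the Pearson correlation of the two ratio columns.
#'
#' @param protein_ratios named numeric vector of per-gene protein log2 ratios.
#' @param rna_ratios named numeric vector of per-gene RNA log2 ratios.
#' @param fpkm named numeric vector of linear FPKM values.
#' @param fpkm_log2_cutoff minimum log2 FPKM, default -1.
#' @return data.frame (`gene`, `protein_log2_ratio`, `rna_log2_ratio`,
#'   `fpkm_log2`) with attribute `pearson_r`.
#' @export
match_omics <- function(protein_ratios, rna_ratios, fpkm,
                        fpkm_log2_cutoff = -1) {
  genes <- Reduce(intersect, list(names(protein_ratios), names(rna_ratios),
                                  names(fpkm)))
  if (!length(genes)) stop("no genes shared between the omics tables")
  fl <- log2(fpkm[genes])
  keep <- is.finite(fl) & fl >= fpkm_log2_cutoff &
    is.finite(protein_ratios[genes]) & is.finite(rna_ratios[genes])
  genes <- genes[keep]
  if (!length(genes)) stop("no genes pass the FPKM cutoff with both ratios")
  out <- data.frame(gene = genes,
                    protein_log2_ratio = unname(protein_ratios[genes]),
                    rna_log2_ratio = unname(rna_ratios[genes]),
                    fpkm_log2 = unname(fl[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "pearson_r") <-
    stats::cor(out$protein_log2_ratio, out$rna_log2_ratio)
  out
}

#' Row-wise z-scoring
#'
#' Centers and scales each row to mean 0 and unit sample standard deviation
#' over its non-missing entries; `NA` cells are preserved. Rows with fewer
#' than 2 values or zero spread become all-`NA` with a warning.
#'
#' @param matrix numeric matrix (proteins x columns).
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(matrix) {
  m <- as.matrix(matrix)
  mu <- rowMeans(m, na.rm = TRUE)
  n <- rowSums(!is.na(m))
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  sd <- sqrt(ss / pmax(n - 1, 1))
  bad <- n < 2 | sd == 0 | !is.finite(sd)
  if (any(bad))
    warning(sum(bad), " row(s) with <2 values or zero spread set to NA")
  out <- (m - mu) / sd
  out[bad, ] <- NA_real_
  out
}
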