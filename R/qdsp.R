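# QDSP: quantitative detergent solubility profiling statistics.
#
# A QDSP table carries, per biological replicate, one sample for each of the
# four solubility fractions (FR1, FR2, FR3, INSOL). Total abundance sums the
# linear values over fractions; solubility change is tested as the
# treatment x fraction interaction of a two-way ANOVA on per-condition
# mean-centred log2 profiles.

QDSP_FRACTIONS <- c("FR1", "FR2", "FR3", "INSOL")

qdsp_check <- function(table) {
  stopifnot(inherits(table, "IntensityTable"))
  s <- table$samples
  if (!all(s$fraction %in% QDSP_FRACTIONS))
    stop("QDSP analysis requires only FR1/FR2/FR3/INSOL samples; subset first")
  key <- interaction(s$condition, s$replicate, drop = TRUE)
  bad <- tapply(s$fraction, key, function(f) length(f) == 0)
  if (any(bad)) stop("replicate(s) with no fraction samples: ",
                     paste(names(bad)[bad], collapse = ", "))
  invisible(table)
}

#' Total protein abundance per biological replicate
#'
#' Sums the linear intensities over the four solubility fractions for each
#' protein and biological replicate (condition x replicate). Missing
#' fractions contribute nothing; a replicate with all four fractions missing
#' is `NA`.
#'
#' @param table a QDSP [intensity_table()].
#' @return numeric matrix proteins x replicates, columns named
#'   `<condition>_R<replicate>`, with attribute `condition` giving each
#'   column's condition.
#' @export
total_abundance <- function(table) {
  qdsp_check(table)
  s <- table$samples
  key <- paste0(s$condition, "_R", s$replicate)
  ukey <- unique(key)
  G <- vapply(ukey, function(k) as.numeric(key == k),
              numeric(nrow(s)))
  vals <- table$values
  has <- (!is.na(vals)) %*% G
  v0 <- vals; v0[is.na(v0)] <- 0
  tot <- v0 %*% G
  tot[has == 0] <- NA_real_
  colnames(tot) <- ukey
  attr(tot, "condition") <- s$condition[match(ukey, key)]
  tot
}

#' Differential total abundance between two conditions
#'
#' Two-sample two-sided t-test (Student pooled variance by default) on the
#' log2 total abundances, with Benjamini-Hochberg correction across all
#' tested proteins.
#'
#' @param totals matrix from [total_abundance()] (or any proteins x samples
#'   matrix of linear totals) with attribute `condition`, or supply
#'   `condition` explicitly.
#' @param condition character vector over columns with exactly two levels;
#'   the first level encountered is the treatment (log2fc = treatment -
#'   control as `levels[1] - levels[2]`).
#' @param var_equal pooled-variance Student test if `TRUE` (default); Welch
#'   otherwise.
#' @return data.frame: `protein_id`, `log2fc`, `t`, `p`, `q`, `tested`.
#' @export
differential_total <- function(totals, condition = attr(totals, "condition"),
                               var_equal = TRUE) {
  stopifnot(!is.null(condition), length(condition) == ncol(totals))
  lev <- unique(condition)
  if (length(lev) != 2) stop("need exactly two conditions, got: ",
                             paste(lev, collapse = ", "))
  lt <- log2(totals)
  res <- row_ttest(lt[, condition == lev[1], drop = FALSE],
                   lt[, condition == lev[2], drop = FALSE],
                   var_equal = var_equal)
  data.frame(protein_id = rownames(totals) %||% seq_len(nrow(totals)),
             log2fc = res$estimate, t = res$t, p = res$p,
             q = bh_fdr(res$p), tested = res$tested,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-condition normalization of solubility profiles
#'
#' Centers each protein's log2 intensities so that the mean of the
#' non-missing log2 values within each condition (over fractions and
#' replicates jointly) is zero. This removes total-abundance differences so
#' the interaction ANOVA responds only to profile shape.
#'
#' @param log2_mat proteins x samples matrix of log2 intensities.
#' @param condition character vector over columns.
#' @param per_replicate if `TRUE`, center each replicate's four fractions
#'   instead of the condition as a whole.
#' @param replicate replicate labels (required when `per_replicate`).
#' @return matrix of the same shape; proteins with a condition entirely
#'   missing keep `NA` everywhere in that condition and are flagged in
#'   attribute `excluded` (no finite center exists for them).
#' @export
normalize_profiles <- function(log2_mat, condition, per_replicate = FALSE,
                               replicate = NULL) {
  log2_mat <- as.matrix(log2_mat)
  groups <- if (per_replicate) {
    stopifnot(!is.null(replicate))
    paste(condition, replicate, sep = "_")
  } else condition
  out <- log2_mat
  excluded <- rep(FALSE, nrow(log2_mat))
  for (g in unique(groups)) {
    j <- groups == g
    mu <- rowMeans(log2_mat[, j, drop = FALSE], na.rm = TRUE)
    excluded <- excluded | !is.finite(mu)
    out[, j] <- log2_mat[, j, drop = FALSE] - mu
  }
  attr(out, "excluded") <- excluded
  out
}

#' Treatment x fraction interaction ANOVA
#'
#' Fixed-effects two-way ANOVA of the normalized log2 profile values on
#' treatment (2 levels) and solubility fraction (4 levels). The interaction
#' sum of squares is the Type-II model comparison `RSS(additive) -
#' RSS(full)`; proteins significant in the interaction term are those whose
#' solubility profile changes between conditions. Proteins with an empty
#' treatment x fraction cell (after missingness) or no residual degrees of
#' freedom are reported untested.
#'
#' @param log2n_mat proteins x samples matrix of normalized log2 values
#'   (from [normalize_profiles()]).
#' @param treatment,fraction factors over columns.
#' @return data.frame: `F`, `df1`, `df2`, `p`, `tested`, `degenerate`.
#' @export
interaction_anova <- function(log2n_mat, treatment, fraction) {
  x <- as.matrix(log2n_mat)
  treatment <- droplevels(as.factor(treatment))
  fraction <- droplevels(as.factor(fraction))
  a <- nlevels(treatment); b <- nlevels(fraction)
  if (a < 2 || b < 2) stop("need >=2 treatment and fraction levels")
  cell <- interaction(treatment, fraction, drop = FALSE)
  n_cells <- a * b
  df1 <- (a - 1) * (b - 1)
  X_add <- stats::model.matrix(~ treatment + fraction)

  n <- nrow(x)
  out <- data.frame(F = rep(NA_real_, n), df1 = df1, df2 = NA_real_,
                    p = NA_real_, tested = FALSE, degenerate = FALSE)
  valid <- !is.na(x)
  pattern <- apply(valid, 1, function(v) paste(as.integer(v), collapse = ""))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    j <- valid[rows[1], ]
    N <- sum(j)
    cells_present <- length(unique(cell[j]))
    if (cells_present < n_cells || N - n_cells < 1) next
    xs <- x[rows, j, drop = FALSE]
    # full model = cell means: RSS is the pooled within-cell SS
    cf <- droplevels(cell[j])
    M <- stats::model.matrix(~ 0 + cf)
    counts <- colSums(M)
    cell_means <- (xs %*% M) / matrix(counts, nrow(xs), length(counts),
                                      byrow = TRUE)
    rss_full <- rowSums(xs^2) -
      rowSums(cell_means^2 * matrix(counts, nrow(xs), length(counts),
                                    byrow = TRUE))
    rss_full <- pmax(rss_full, 0)
    fit <- stats::lm.fit(X_add[j, , drop = FALSE], t(xs))
    res <- as.matrix(fit$residuals)
    rss_add <- colSums(res^2)
    df2 <- N - n_cells
    ss_int <- pmax(rss_add - rss_full, 0)
    Fv <- (ss_int / df1) / (rss_full / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    degen <- rss_full <= .Machine$double.eps * pmax(rss_add, 1)
    p[degen & ss_int > 1e-12] <- 0
    p[degen & ss_int <= 1e-12] <- 1
    Fv[degen & ss_int <= 1e-12] <- 0
    out$F[rows] <- Fv
    out$df2[rows] <- df2
    out$p[rows] <- p
    out$tested[rows] <- TRUE
    out$degenerate[rows] <- degen
  }
  out
}

#' Share of MS intensity in the insoluble fraction
#'
#' Per protein and condition: the summed linear INSOL intensity over all
#' replicates divided by the summed intensity over all four fractions.
#' Missing cells contribute zero mass; an all-missing condition is `NA`.
#'
#' @param table a QDSP [intensity_table()].
#' @return matrix proteins x conditions of shares in `[0, 1]`.
#' @export
insoluble_share <- function(table) {
  qdsp_check(table)
  s <- table$samples
  conds <- unique(s$condition)
  v0 <- table$values; v0[is.na(v0)] <- 0
  out <- vapply(conds, function(cn) {
    j <- s$condition == cn
    num <- rowSums(v0[, j & s$fraction == "INSOL", drop = FALSE])
    den <- rowSums(v0[, j, drop = FALSE])
    ifelse(den > 0, num / den, NA_real_)
  }, numeric(nrow(v0)))
  out <- matrix(out, nrow = nrow(v0),
                dimnames = list(rownames(v0), conds))
  out
}

#' Full QDSP per-protein statistics
#'
#' Runs the whole QDSP analysis: total abundance and its differential t-test,
#' per-condition profile normalization, the treatment x fraction interaction
#' ANOVA, insoluble-share summaries and the abundance rank.
#'
#' @param table a QDSP [intensity_table()] with two conditions.
#' @param fdr FDR threshold annotated in the output, default 0.05.
#' @param var_equal Student (TRUE) or Welch t-test for the total-abundance
#'   comparison.
#' @return data.frame with one row per protein: interaction `interaction_F`,
#'   `interaction_p`, `interaction_q`, `total_log2fc`, `total_t_p`,
#'   `total_t_q`, per-condition `insoluble_share_*`, `delta_insoluble_share`
#'   (treatment minus control), `abundance_rank` (1 = most abundant tested
#'   protein) and `significant_profile` at the given FDR.
#' @export
qdsp_stats <- function(table, fdr = 0.05, var_equal = TRUE) {
  qdsp_check(table)
  s <- table$samples
  conds <- unique(s$condition)
  if (length(conds) != 2) stop("QDSP statistics need exactly two conditions")
  treat <- setdiff(conds, "PBS")[1] %||% conds[1]
  ctrl <- setdiff(conds, treat)[1]

  totals <- total_abundance(table)
  cond_t <- attr(totals, "condition")
  diff <- row_ttest(log2(totals[, cond_t == treat, drop = FALSE]),
                    log2(totals[, cond_t == ctrl, drop = FALSE]),
                    var_equal = var_equal)
  lm2 <- log2_matrix(table)
  norm <- normalize_profiles(lm2, s$condition)
  ia <- interaction_anova(norm, s$condition, s$fraction)
  shares <- insoluble_share(table)

  mean_log2_tot <- rowMeans(log2(totals), na.rm = TRUE)
  tested_rank <- is.finite(mean_log2_tot)
  abundance_rank <- rep(NA_integer_, nrow(totals))
  abundance_rank[tested_rank] <- rank(-mean_log2_tot[tested_rank],
                                      ties.method = "first")

  out <- data.frame(
    protein_id = table$proteins$protein_id,
    gene_name = table$proteins$gene_name,
    interaction_F = ia$F,
    interaction_p = ia$p,
    interaction_q = bh_fdr(ia$p),
    interaction_tested = ia$tested,
    total_log2fc = diff$estimate,
    total_t_p = diff$p,
    total_t_q = bh_fdr(diff$p),
    abundance_rank = abundance_rank,
    stringsAsFactors = FALSE)
  out[[paste0("insoluble_share_", treat)]] <- shares[, treat]
  out[[paste0("insoluble_share_", ctrl)]] <- shares[, ctrl]
  out$delta_insoluble_share <- shares[, treat] - shares[, ctrl]
  out$significant_profile <- !is.na(out$interaction_q) & out$interaction_q < fdr
  attr(out, "conditions") <- c(treatment = treat, control = ctrl)
  out
}

#' Principal component analysis of fraction samples
#'
#' PCA of a complete samples x proteins matrix (typically z-scored upstream):
#' scores are sample projections, loadings orthonormal protein weights, and
#' the sign convention makes each loading vector's largest-magnitude element
#' positive.
#'
#' @param matrix samples x proteins numeric matrix without missing values.
#' @param n_components number of components, default `min(dim) - 1`.
#' @return list with `scores`, `loadings`, `variance_explained`.
#' @export
pca_fractions <- function(matrix, n_components = NULL) {
  m <- as.matrix(matrix)
  if (anyNA(m))
    stop("matrix contains missing values; filter or impute upstream")
  k_max <- min(nrow(m) - 1L, ncol(m))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max) stop("n_components exceeds min(dim)")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = load,
       variance_explained = ve[seq_len(k)])
}

#' Hierarchical clustering of z-scored profiles
#'
#' Agglomerative clustering with correlation distance `1 - Pearson r`
#' (default) or Euclidean distance, and average linkage by default.
#'
#' @param matrix rows to cluster (complete, typically z-scored).
#' @param linkage linkage method passed to [stats::hclust()].
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, `dist` and, when `k` given, `clusters`.
#' @export
cluster_profiles <- function(matrix, linkage = "average",
                             distance = c("correlation", "euclidean"),
                             k = NULL) {
  m <- as.matrix(matrix)
  distance <- match.arg(distance)
  if (nrow(m) < 2) stop("need >=2 rows to cluster")
  if (anyNA(m)) stop("matrix contains missing values")
  if (distance == "correlation") {
    if (any(apply(m, 1, stats::sd) == 0))
      stop("constant row(s): correlation distance undefined")
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m)
  }
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, dist = d)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}
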