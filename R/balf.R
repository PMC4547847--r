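# BALF vs tissue compartment analysis.
#
# The BALF enrichment score is the SAM d-statistic (Tusher's formula one):
#   d = (mean_BALF - mean_tissue) / (s + s0)
# with the gene-specific scatter
#   s = sqrt( (1/n1 + 1/n2) / (n1 + n2 - 2) * (SS1 + SS2) )
# and the exchangeability constant s0 damping scores at low variance.
# At s0 = 0, d is algebraically the pooled-variance two-sample t statistic.

#' SAM scoring parameters
#'
#' @param s0 fixed exchangeability constant (same units as the scatter s);
#'   ignored unless `s0_rule = "FIXED"` with a non-`NULL` value.
#' @param s0_rule `"PERCENTILE"` (default): s0 is a percentile of the
#'   s-distribution; `"FIXED"`: use `s0` as given.
#' @param s0_percentile percentile in `[0, 100]`, default 5.
#' @param n_permutations permutation budget per protein for the null of d
#'   (exact enumeration is used instead when the number of distinct group
#'   assignments is at most this budget), default 10000.
#' @param seed RNG seed for sampled permutations.
#' @return list of class `sam_params`.
#' @export
sam_params <- function(s0 = NULL, s0_rule = c("PERCENTILE", "FIXED"),
                       s0_percentile = 5, n_permutations = 10000, seed = 1) {
  s0_rule <- match.arg(s0_rule)
  if (s0_rule == "FIXED" && (is.null(s0) || s0 < 0))
    stop("FIXED rule needs a non-negative s0")
  stopifnot(s0_percentile >= 0, s0_percentile <= 100, n_permutations >= 1)
  structure(list(s0 = s0, s0_rule = s0_rule, s0_percentile = s0_percentile,
                 n_permutations = n_permutations, seed = seed),
            class = "sam_params")
}

# Tusher scatter for matrices: x, y proteins x samples (log2)
sam_scatter <- function(x, y) {
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  ss1 <- rowSums((x - rowMeans(x, na.rm = TRUE))^2, na.rm = TRUE)
  ss2 <- rowSums((y - rowMeans(y, na.rm = TRUE))^2, na.rm = TRUE)
  sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * (ss1 + ss2))
}

#' SAM-style BALF enrichment scores
#'
#' Computes, per protein, the d-statistic comparing BALF to tissue log2
#' intensities, its significance and BH q-value. With `s0 = 0` the p-value
#' comes from the pooled t reference (d is then exactly the t statistic);
#' with `s0 > 0` the t reference is invalid and a per-protein label
#' permutation null is used (exact enumeration when feasible, otherwise
#' sampled with a fixed seed).
#'
#' @param balf_mat,tissue_mat proteins x samples matrices of log2
#'   intensities (same row order).
#' @param params a [sam_params()].
#' @param fdr FDR threshold for the `elf_enriched` call, default 0.05.
#' @return data.frame: `protein_id`, `d`, `s`, `s0`, `mean_balf`,
#'   `mean_tissue`, `p`, `q`, `elf_enriched`, `tested`.
#' @export
sam_scores <- function(balf_mat, tissue_mat, params = sam_params(),
                       fdr = 0.05) {
  x <- as.matrix(balf_mat); y <- as.matrix(tissue_mat)
  stopifnot(nrow(x) == nrow(y))
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  tested <- n1 >= 2 & n2 >= 2
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  s <- sam_scatter(x, y)
  s0 <- switch(params$s0_rule,
               FIXED = params$s0,
               PERCENTILE = stats::quantile(s[tested & is.finite(s)],
                                            params$s0_percentile / 100,
                                            names = FALSE))
  d <- (m1 - m2) / (s + s0)
  degenerate <- tested & (s + s0) == 0
  d[degenerate] <- NA_real_
  tested <- tested & !degenerate

  if (s0 == 0) {
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(abs(d), df, lower.tail = FALSE)
  } else {
    p <- sam_permutation_p(x, y, d, s0, params)
  }
  p[!tested] <- NA_real_
  d[!tested] <- NA_real_
  q <- bh_fdr(p)
  data.frame(protein_id = rownames(x) %||% seq_len(nrow(x)),
             d = d, s = s, s0 = s0, mean_balf = m1, mean_tissue = m2,
             p = p, q = q,
             elf_enriched = !is.na(q) & d > 0 & q < fdr,
             tested = tested, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Single-protein SAM enrichment score
#'
#' Convenience wrapper of [sam_scores()] for one protein.
#'
#' @param balf_values,tissue_values numeric vectors of log2 intensities.
#' @param params a [sam_params()]; note the percentile rule degenerates to
#'   s0 = s for a single protein, so a `FIXED` s0 is usually wanted here.
#' @param fdr FDR threshold for the enrichment call.
#' @return one-row data.frame as in [sam_scores()].
#' @export
sam_enrichment_score <- function(balf_values, tissue_values,
                                 params = sam_params(s0 = 0,
                                                     s0_rule = "FIXED"),
                                 fdr = 0.05) {
  sam_scores(matrix(balf_values, 1), matrix(tissue_values, 1),
             params = params, fdr = fdr)
}

# Per-protein permutation null of |d|, vectorised over proteins sharing a
# missingness pattern; the permutation assignment matrix is cached per
# (n1, n2) pair and reused across patterns.
sam_permutation_p <- function(x, y, d, s0, params) {
  n <- nrow(x)
  p <- rep(NA_real_, n)
  xy <- cbind(x, y)
  k1 <- ncol(x)
  valid <- !is.na(xy)
  pattern <- apply(valid, 1, function(v) paste(as.integer(v), collapse = ""))
  set.seed(params$seed)
  assign_cache <- new.env(parent = emptyenv())
  B_max <- params$n_permutations

  perm_assignments <- function(n1, n2) {
    key <- paste(n1, n2, sep = "_")
    if (!is.null(assign_cache[[key]])) return(assign_cache[[key]])
    n_tot <- n1 + n2
    n_comb <- choose(n_tot, n1)
    if (n_comb <= B_max) {
      idx <- utils::combn(n_tot, n1)
      P <- matrix(0, ncol(idx), n_tot)
      P[cbind(rep(seq_len(ncol(idx)), each = n1), as.vector(idx))] <- 1
      exact <- TRUE
    } else {
      P <- t(replicate(B_max, {
        v <- numeric(n_tot); v[sample.int(n_tot, n1)] <- 1; v
      }))
      exact <- FALSE
    }
    res <- list(P = P, exact = exact)
    assign_cache[[key]] <- res
    res
  }

  chunk_size <- 500L
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    j <- valid[rows[1], ]
    n1 <- sum(j[seq_len(k1)]); n2 <- sum(j[-seq_len(k1)])
    if (n1 < 2 || n2 < 2 || !all(is.finite(d[rows]))) next
    pa <- perm_assignments(n1, n2)
    P <- pa$P
    B <- nrow(P)
    cols <- c(which(j[seq_len(k1)]), k1 + which(j[-seq_len(k1)]))
    n_tot <- n1 + n2
    coef <- (1 / n1 + 1 / n2) / (n_tot - 2)
    for (start in seq(1, length(rows), by = chunk_size)) {
      rr <- rows[start:min(start + chunk_size - 1L, length(rows))]
      X <- t(xy[rr, cols, drop = FALSE])           # n_tot x k proteins
      X2 <- X^2
      tot <- colSums(X); tot2 <- colSums(X2)
      s1 <- P %*% X                                 # B x k group-1 sums
      q1 <- P %*% X2
      mu1 <- s1 / n1
      mu2 <- (rep(tot, each = B) - s1) / n2
      ssw <- (q1 - n1 * mu1^2) + ((rep(tot2, each = B) - q1) - n2 * mu2^2)
      ssw[ssw < 0] <- 0
      d_null <- (mu1 - mu2) / (sqrt(coef * ssw) + s0)
      exceed <- colSums(abs(d_null) >= matrix(abs(d[rr]), B, length(rr),
                                              byrow = TRUE))
      p[rr] <- if (pa$exact) exceed / B else (exceed + 1) / (B + 1)
    }
  }
  p
}

#' Day-14 BALF differential test
#'
#' Two-sample two-sided t-test of BALF log2 intensities, treatment versus
#' control, at day 14 (the fibrotic peak), with BH correction.
#'
#' @param table an [intensity_table()] with BALF samples.
#' @param day time point tested, default 14.
#' @param control control condition label, default `"PBS"`.
#' @param var_equal Student pooled test if `TRUE` (default).
#' @return data.frame: `protein_id`, `log2fc`, `t`, `p`, `q`, `tested`.
#' @export
balf_day14_ttest <- function(table, day = 14, control = "PBS",
                             var_equal = TRUE) {
  stopifnot(inherits(table, "IntensityTable"))
  s <- table$samples
  sel <- s$compartment == "BALF" & !is.na(s$timepoint_days) &
    s$timepoint_days == day
  if (!any(sel)) stop("no BALF samples at day ", day)
  sub <- subset_samples(table, sel)
  lm2 <- log2_matrix(sub)
  is_ctrl <- sub$samples$condition == control
  res <- row_ttest(lm2[, !is_ctrl, drop = FALSE],
                   lm2[, is_ctrl, drop = FALSE], var_equal = var_equal)
  data.frame(protein_id = sub$proteins$protein_id,
             log2fc = res$estimate, t = res$t, p = res$p, q = bh_fdr(res$p),
             tested = res$tested, stringsAsFactors = FALSE)
}

#' BALF expression-ratio time course
#'
#' Computes per-replicate BALF log2 ratios against the control average
#' pooled across all replicates and time points (the compartment's ratio
#' convention), then a one-way ANOVA over time on the treated ratios.
#'
#' @param table an [intensity_table()] with BALF samples in both conditions.
#' @param params an [imputation_params()].
#' @param control control condition label, default `"PBS"`.
#' @return list with `ratios` (a `ratio_matrix`) and `anova` (data.frame as
#'   [anova_timecourse()]).
#' @export
balf_timecourse <- function(table, params = imputation_params(),
                            control = "PBS") {
  stopifnot(inherits(table, "IntensityTable"))
  sel <- table$samples$compartment == "BALF"
  if (!any(sel)) stop("no BALF samples in table")
  sub <- subset_samples(table, sel)
  ratios <- compute_ratios(sub, params = params, control = control,
                           denominator = "mean")
  list(ratios = ratios, anova = anova_timecourse(ratios))
}
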