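# Vectorised row-wise test statistics for protein-level scans.
# Formulas are cross-checked against stats::t.test / stats::aov /
# stats::cor.test in the test suite.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; `NA` p-values pass through and do
#' not count toward the number of tests.
#'
#' @param p_values numeric vector in `[0, 1]` (NA allowed).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

# Two-sample Student (pooled) or Welch t-test across matrix rows.
# x, y: proteins x samples matrices (same rows). Returns a data.frame with
# mean_x, mean_y, estimate (mean_x - mean_y), t, df, p, tested, degenerate.
row_ttest <- function(x, y, var_equal = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
  tested <- n1 >= 2 & n2 >= 2
  est <- m1 - m2
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- (ss1 + ss2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- ss1 / (n1 - 1) / n1
    v2 <- ss2 / (n2 - 1) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- est / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degenerate <- tested & se == 0
  # zero spread in both groups: identical means -> p = 1, else p = 0
  p[degenerate & est == 0] <- 1
  t[degenerate & est == 0] <- 0
  p[degenerate & est != 0] <- 0
  if (any(degenerate & est != 0))
    warning(sum(degenerate & est != 0),
            " protein(s) with zero within-group variance and unequal means")
  p[!tested] <- NA_real_; t[!tested] <- NA_real_
  data.frame(mean_x = m1, mean_y = m2, estimate = est, t = t, df = df, p = p,
             tested = tested, degenerate = degenerate)
}

# One-way fixed-effects ANOVA across matrix rows.
# x: proteins x samples, groups: factor over columns. A group enters a row's
# decomposition when it has >=1 value there; the row is tested when >=2
# groups have >=2 values (and residual df > 0).
row_oneway <- function(x, groups) {
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  G <- stats::model.matrix(~ 0 + groups)            # samples x k indicator
  valid <- !is.na(x)
  x0 <- x; x0[!valid] <- 0
  n_g <- valid %*% G                                 # per-row per-group n
  s_g <- x0 %*% G
  m_g <- s_g / n_g                                   # NaN where n_g = 0
  n_tot <- rowSums(n_g)
  grand <- rowSums(s_g) / n_tot
  k_used <- rowSums(n_g > 0)
  ssb <- rowSums(n_g * (m_g - grand)^2, na.rm = TRUE)
  sst <- rowSums((x - grand)^2, na.rm = TRUE)
  ssw <- sst - ssb
  ssw[ssw < 0] <- 0                                  # numeric guard
  df1 <- k_used - 1
  df2 <- n_tot - k_used
  tested <- rowSums(n_g >= 2) >= 2 & df1 >= 1 & df2 >= 1
  msb <- ssb / df1
  msw <- ssw / df2
  F <- msb / msw
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  degenerate <- tested & msw == 0
  p[degenerate & ssb > 0] <- 0
  zero_all <- degenerate & ssb <= .Machine$double.eps * pmax(sst, 1)
  p[zero_all] <- 1
  F[zero_all] <- 0
  p[!tested] <- NA_real_; F[!tested] <- NA_real_
  data.frame(F = F, df1 = df1, df2 = df2, p = p, tested = tested,
             degenerate = degenerate)
}

# Per-row ordinary least squares of row values (y) on a shared covariate (x),
# plus the Pearson correlation and its two-sided t-based p on n-2 df.
row_ols <- function(y, x) {
  y <- as.matrix(y)
  stopifnot(length(x) == ncol(y))
  valid <- !is.na(y) & matrix(rep(!is.na(x), each = nrow(y)), nrow = nrow(y))
  y0 <- y; y0[!valid] <- 0
  x_mat <- matrix(rep(x, each = nrow(y)), nrow = nrow(y))
  x0 <- x_mat; x0[!valid] <- 0
  n <- rowSums(valid)
  sx <- rowSums(x0); sy <- rowSums(y0)
  mx <- sx / n; my <- sy / n
  sxx <- rowSums((x0 - mx)^2 * valid)
  syy <- rowSums((y0 - my)^2 * valid)
  sxy <- rowSums((x0 - mx) * (y0 - my) * valid)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r <- sxy / sqrt(sxx * syy)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  tested <- n >= 3 & sxx > 0 & syy > 0
  p[tested & abs(r) >= 1] <- 0
  slope[!tested] <- NA_real_; intercept[!tested] <- NA_real_
  r[!tested] <- NA_real_; p[!tested] <- NA_real_
  data.frame(slope = slope, intercept = intercept, pearson_r = r, n = n,
             p = p, tested = tested)
}
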