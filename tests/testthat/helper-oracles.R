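# Independent brute-force / closed-form oracles used to validate the
# package's vectorised statistics. These deliberately take the slow,
# textbook route and never share code with the implementation.

oracle_ttest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

oracle_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- nlevels(droplevels(groups)); n <- length(values)
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = pf(F, k - 1, n - k, lower.tail = FALSE))
}

# interaction term by explicit model comparison through stats::lm/anova
oracle_interaction <- function(y, treatment, fraction) {
  d <- data.frame(y = y, t = factor(treatment), f = factor(fraction))
  a <- anova(lm(y ~ t + f, d), lm(y ~ t * f, d))
  list(F = a$F[2], p = a$`Pr(>F)`[2])
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# two-sided Fisher p by full enumeration of the hypergeometric support
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U and rank-biserial score by exhaustive pair comparison
oracle_rank_biserial <- function(values, member_idx) {
  inv <- values[member_idx]
  outv <- values[-member_idx]
  U <- 0
  for (a in inv) for (b in outv)
    U <- U + (a > b) + 0.5 * (a == b)
  n_pair <- length(inv) * length(outv)
  list(U = U, score = (2 * U - n_pair) / n_pair)
}

# peptide counting by walking the chain one residue at a time
oracle_tryptic <- function(seq, min_len = 7, max_len = 30) {
  aa <- strsplit(seq, "")[[1]]
  count <- 0; len <- 0
  for (i in seq_along(aa)) {
    len <- len + 1
    cleave <- aa[i] %in% c("K", "R") &&
      (i == length(aa) || aa[i + 1] != "P")
    if (cleave || i == length(aa)) {
      if (len >= min_len && len <= max_len) count <- count + 1
      len <- 0
    }
  }
  count
}

oracle_sam_d <- function(x, y, s0 = 0) {
  n1 <- length(x); n2 <- length(y)
  s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) *
              (sum((x - mean(x))^2) + sum((y - mean(y))^2)))
  (mean(x) - mean(y)) / (s + s0)
}

# small intensity-table builder for hand-written fixtures
make_table <- function(values, condition, fraction = NULL, replicate = NULL,
                       timepoint_days = NA, compartment = "TISSUE",
                       compliance = NA, mouse_id = NULL) {
  ns <- ncol(values)
  samples <- data.frame(
    sample_id = paste0("S", seq_len(ns)),
    condition = condition,
    timepoint_days = timepoint_days,
    fraction = fraction %||% "TOTAL",
    replicate = replicate %||% seq_len(ns),
    mouse_id = mouse_id %||% paste0("m", seq_len(ns)),
    compartment = compartment,
    compliance = compliance,
    stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = paste0("P", seq_len(nrow(values))),
                         gene_name = paste0("G", seq_len(nrow(values))),
                         stringsAsFactors = FALSE)
  intensity_table(values, proteins, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
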