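test_that("total abundance sums linear fraction values and keeps NA groups", {
  vals <- rbind(c(1, 2, 3, 4), c(NA, NA, NA, NA), c(5, NA, NA, 5))
  tab <- make_table(vals, condition = rep("PBS", 4),
                    fraction = c("FR1", "FR2", "FR3", "INSOL"),
                    replicate = rep(1, 4), mouse_id = rep("m1", 4))
  tot <- total_abundance(tab)
  expect_equal(unname(tot[, 1]), c(10, NA, 10))
})

test_that("differential totals match the pooled-t oracle and handle nulls", {
  # identical groups: t = 0, p = 1
  v <- rbind(rep(2^c(1, 2, 3, 1, 2, 3), 1))
  tot <- matrix(2^c(1, 2, 3, 1, 2, 3), 1)
  r <- differential_total(tot, condition = rep(c("A", "B"), each = 3))
  expect_equal(r$p, 1)
  expect_equal(r$log2fc, 0)
  # hand-built groups against the textbook pooled formula
  x <- c(0, 0, 1, 1); y <- c(2, 2, 3, 3)
  r2 <- differential_total(matrix(2^c(x, y), 1),
                           condition = rep(c("A", "B"), each = 4))
  o <- oracle_ttest(x, y)
  expect_equal(r2$p, o$p, tolerance = 1e-10)
  expect_equal(r2$t, o$t, tolerance = 1e-10)
  # 100 random instances against the oracle
  set.seed(21)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    r3 <- differential_total(matrix(2^c(x, y), 1),
                             condition = rep(c("A", "B"), c(n1, n2)))
    o3 <- oracle_ttest(x, y)
    expect_equal(r3$p, o3$p, tolerance = 1e-10)
  }
})

test_that("profile normalization zeroes each condition's log2 mean", {
  m <- matrix(c(10, 12, 14, 16, 20, 22, 24, 26), 1)
  cond <- rep(c("PBS", "BLEO"), each = 4)
  norm <- normalize_profiles(m, cond)
  expect_equal(norm[1, 1:4], c(-3, -1, 1, 3))
  expect_equal(norm[1, 5:8], c(-3, -1, 1, 3))
  # constant condition maps to zero
  m2 <- matrix(rep(c(5, 7), each = 4), 1)
  expect_equal(unname(normalize_profiles(m2, cond)[1, ]), rep(0, 8))
  # invariant: per-condition mean 0 for any input with missing cells
  set.seed(4)
  m3 <- matrix(rnorm(80, 25, 3), 10)
  m3[sample(80, 8)] <- NA
  n3 <- normalize_profiles(m3, cond)
  for (cn in unique(cond))
    expect_equal(rowMeans(n3[, cond == cn], na.rm = TRUE), rep(0, 10),
                 tolerance = 1e-12)
})

test_that("interaction ANOVA matches an independent model-comparison oracle", {
  set.seed(31)
  treatment <- rep(c("PBS", "BLEO"), each = 8)
  fraction <- rep(rep(c("FR1", "FR2", "FR3", "INSOL"), each = 2), 2)
  # additive zero-noise data -> no interaction, p = 1
  add <- outer(c(0, 1), c(0, 2, 4, 6), `+`)  # treatment x fraction means
  y_add <- add[cbind(as.integer(factor(treatment, c("PBS", "BLEO"))),
                     as.integer(factor(fraction,
                                       c("FR1", "FR2", "FR3", "INSOL"))))]
  res_add <- interaction_anova(matrix(y_add, 1), treatment, fraction)
  expect_equal(res_add$p, 1)
  # 100 random unbalanced-ish instances against lm/anova
  for (i in 1:100) {
    y <- rnorm(16, sd = 1) + ifelse(treatment == "BLEO" & fraction == "INSOL",
                                    rnorm(1), 0)
    res <- interaction_anova(matrix(y, 1), treatment, fraction)
    o <- oracle_interaction(y, treatment, fraction)
    expect_equal(res$F, o$F, tolerance = 1e-10)
    expect_equal(res$p, o$p, tolerance = 1e-10)
  }
  # missing cells: listwise deletion must agree with lm on the kept cells
  for (i in 1:30) {
    y <- rnorm(16)
    y[sample(16, 3)] <- NA
    res <- interaction_anova(matrix(y, 1), treatment, fraction)
    keep <- !is.na(y)
    if (res$tested) {
      o <- oracle_interaction(y[keep], treatment[keep], fraction[keep])
      expect_equal(res$p, o$p, tolerance = 1e-10)
    } else {
      # untested only when a design cell emptied out or df ran out
      expect_lt(length(unique(interaction(treatment, fraction)[keep])), 8.5)
    }
  }
})

test_that("interaction ANOVA reports empty-cell proteins untested", {
  treatment <- rep(c("PBS", "BLEO"), each = 8)
  fraction <- rep(rep(c("FR1", "FR2", "FR3", "INSOL"), each = 2), 2)
  y <- rnorm(16)
  y[treatment == "BLEO" & fraction == "INSOL"] <- NA
  res <- interaction_anova(matrix(y, 1), treatment, fraction)
  expect_false(res$tested)
  expect_true(is.na(res$p))
})

test_that("interaction p is invariant to per-condition constants", {
  set.seed(12)
  treatment <- rep(c("PBS", "BLEO"), each = 8)
  fraction <- rep(rep(c("FR1", "FR2", "FR3", "INSOL"), each = 2), 2)
  y <- rnorm(16)
  p0 <- interaction_anova(matrix(y, 1), treatment, fraction)$p
  y_shift <- y + ifelse(treatment == "PBS", 3.7, -1.2)
  p1 <- interaction_anova(matrix(y_shift, 1), treatment, fraction)$p
  expect_equal(p0, p1, tolerance = 1e-9)
})

test_that("insoluble share pools linear replicate mass", {
  vals <- rbind(c(1, 1, 1, 1), c(NA, NA, NA, 5))
  tab <- make_table(vals, condition = rep("PBS", 4),
                    fraction = c("FR1", "FR2", "FR3", "INSOL"),
                    replicate = rep(1, 4), mouse_id = rep("m1", 4))
  sh <- insoluble_share(tab)
  expect_equal(unname(sh[, "PBS"]), c(0.25, 1.0))
  # two replicates (1,1,1,1) and (1,1,1,5): pooled (1+5)/(4+8)
  vals2 <- matrix(c(1, 1, 1, 1, 1, 1, 1, 5), 1)
  tab2 <- make_table(vals2, condition = rep("PBS", 8),
                     fraction = rep(c("FR1", "FR2", "FR3", "INSOL"), 2),
                     replicate = rep(1:2, each = 4),
                     mouse_id = rep(c("m1", "m2"), each = 4))
  expect_equal(unname(insoluble_share(tab2)[, "PBS"]), 0.5)
})

test_that("qdsp_stats assembles ranks, shares and q-values coherently", {
  cfg <- generator_config(n_proteins = 200, seed = 3)
  sim <- generate_qdsp_dataset(cfg)
  st <- qdsp_stats(sim$table)
  ok <- !is.na(st$abundance_rank)
  expect_setequal(st$abundance_rank[ok], seq_len(sum(ok)))
  expect_equal(st$delta_insoluble_share,
               st$insoluble_share_BLEO - st$insoluble_share_PBS)
  # q monotone in p
  o <- order(st$interaction_p)
  q <- st$interaction_q[o]
  expect_true(all(diff(q[!is.na(q)]) >= -1e-15))
})

test_that("PCA reproduces the eigendecomposition of the covariance", {
  set.seed(41)
  m <- matrix(rnorm(160), 20, 8)
  pc <- pca_fractions(m, n_components = 5)
  expect_equal(crossprod(pc$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  ev <- eigen(cov(m), symmetric = TRUE)$values
  comp_var <- apply(pc$scores, 2, var)
  expect_equal(unname(comp_var), ev[1:5], tolerance = 1e-8)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  # duplicated samples land on identical scores
  m2 <- rbind(m, m[1, ])
  pc2 <- pca_fractions(m2, n_components = 3)
  expect_equal(pc2$scores[21, ], pc2$scores[1, ], tolerance = 1e-10)
  expect_error(pca_fractions(rbind(c(1, NA), c(2, 3))), "missing")
})

test_that("correlation-distance clustering matches a brute-force merge", {
  x <- c(1, 2, 3, 4)
  m <- rbind(a = x, b = x, c = -x, d = c(4, 1, 3, 2), e = c(10, 2, 5, 1),
             f = c(0, 5, 1, 6))
  cl <- cluster_profiles(m)
  # identical rows merge first at height 0
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)
  first <- sort(abs(cl$hclust$merge[1, ]))
  expect_equal(first, c(1, 2))
  # anticorrelated rows sit at distance 2
  expect_equal(as.matrix(cl$dist)["a", "c"], 2, tolerance = 1e-12)
  # brute-force average-linkage agglomeration oracle on the same distances
  D <- as.matrix(cl$dist)
  groups <- as.list(seq_len(6))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      d_ij <- mean(D[groups[[i]], groups[[j]]])
      if (d_ij < best[1]) best <- c(d_ij, j, i)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  expect_equal(cl$hclust$height, heights, tolerance = 1e-12)
  expect_error(cluster_profiles(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
})
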