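test_that("BH q-values match the step-up oracle and keep invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(81)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone: p_i <= p_j => q_i <= q_j
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-15)
  }
  # NA pass-through does not count toward the number of tests
  expect_equal(bh_fdr(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
})

test_that("Fisher enrichment equals the enumeration oracle on small tables", {
  set.seed(82)
  bg <- sprintf("g%03d", 1:100)
  fg <- bg[1:10]
  ann <- annotation_collection(list(
    T1 = list(label = "t1", category = "c",
              members = bg[c(1:8, 11:22)]),       # 8 of fg, 20 of bg
    T2 = list(label = "t2", category = "c", members = bg[41:80]),
    ALL = list(label = "everything", category = "c", members = bg)))
  res <- fisher_enrichment(fg, bg, ann)
  expect_equal(res$p[res$term_id == "ALL"], 1)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$fg_in, 8)
  expect_equal(r1$p, oracle_fisher_p(8, 2, 12, 78), tolerance = 1e-10)
  # depleted term
  r2 <- res[res$term_id == "T2", ]
  expect_equal(r2$p, oracle_fisher_p(r2$fg_in, r2$fg_out, r2$bg_in, r2$bg_out),
               tolerance = 1e-10)
  # margins always add up
  expect_true(all(res$fg_in + res$fg_out == 10))
  expect_true(all(res$bg_in + res$bg_out == 90))
  # random 2x2 tables with margins <= 40 against the oracle
  for (i in 1:50) {
    nb <- sample(10:40, 1)
    nf <- sample(2:(nb - 2), 1)
    nt <- sample(2:(nb - 1), 1)
    bgi <- sprintf("x%02d", seq_len(nb))
    anni <- annotation_collection(list(
      TT = list(label = "tt", category = "c", members = sample(bgi, nt))))
    fgi <- sample(bgi, nf)
    ri <- fisher_enrichment(fgi, bgi, anni)
    a <- ri$fg_in; b <- ri$fg_out; c2 <- ri$bg_in; d <- ri$bg_out
    expect_equal(ri$p, oracle_fisher_p(a, b, c2, d), tolerance = 1e-10)
  }
  expect_error(fisher_enrichment(character(0), bg, ann), "empty foreground")
})

test_that("1D enrichment score is the brute-force rank-biserial", {
  set.seed(83)
  ids <- sprintf("g%03d", 1:40)
  vals <- setNames(rnorm(40), ids)
  # members occupy exactly the top ranks -> score +1
  top <- ids[order(vals, decreasing = TRUE)][1:8]
  ann_top <- annotation_collection(list(
    TOP = list(label = "top", category = "c", members = top)))
  expect_equal(enrichment_1d(vals, ann_top)$score, 1)
  # random terms against the pair-counting oracle, including ties
  vals_t <- vals; vals_t[1:6] <- vals_t[7:12]   # force ties
  for (i in 1:25) {
    memb <- sample(ids, sample(5:15, 1))
    ann <- annotation_collection(list(
      M = list(label = "m", category = "c", members = memb)))
    res <- enrichment_1d(vals_t, ann)
    o <- oracle_rank_biserial(vals_t, which(ids %in% memb))
    expect_equal(res$score, o$score, tolerance = 1e-12)
    expect_equal(res$U, o$U, tolerance = 1e-12)
    # complement antisymmetry is exact
    annc <- annotation_collection(list(
      MC = list(label = "mc", category = "c", members = setdiff(ids, memb))))
    resc <- enrichment_1d(vals_t, annc)
    expect_equal(resc$score, -res$score, tolerance = 1e-15)
  }
})

test_that("1D normal-approximation p agrees with exact enumeration", {
  # exhaustive small designs: n_in <= 8, n_total <= 30, tie-free values
  set.seed(84)
  worst <- 0
  for (n_total in c(12, 20, 30)) for (n_in in c(3, 5, 8)) {
    vals <- setNames(sample(seq_len(1000), n_total),
                     sprintf("i%03d", seq_len(n_total)))
    for (rep in 1:10) {
      memb <- sample(names(vals), n_in)
      ann <- annotation_collection(list(
        M = list(label = "m", category = "c", members = memb)))
      # exact route (tie-free, small): package default
      p_exact <- enrichment_1d(vals, ann, min_members = 3)$p
      # normal-approximation route via the internal core
      ranks <- rank(vals)
      core <- qdspr:::rank_enrichment_core(ranks, which(names(vals) %in% memb),
                                           n_total, table(vals),
                                           exact_limit = 0)
      worst <- max(worst, abs(core$p - p_exact))
    }
  }
  expect_lt(worst, 0.01)
})

test_that("null 1D enrichment is centred and level-accurate", {
  set.seed(85)
  vals <- setNames(rnorm(2000), sprintf("g%04d", 1:2000))
  scores <- ps <- numeric(1000)
  for (i in 1:1000) {
    ann <- annotation_collection(list(
      M = list(label = "m", category = "c",
               members = sample(names(vals), 25))))
    r <- enrichment_1d(vals, ann)
    scores[i] <- r$score; ps[i] <- r$p
  }
  expect_lt(abs(mean(scores)), 0.02)
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("2D enrichment marginals collapse to the 1D scores", {
  set.seed(86)
  ids <- sprintf("g%03d", 1:60)
  x <- setNames(rnorm(60), ids)
  ann <- annotation_collection(list(
    M = list(label = "m", category = "c", members = sample(ids, 12))))
  # y identical to x: score_y = score_x, and both equal the 1D score
  r <- enrichment_2d(x, x, ann, n_permutations = 500)
  r1 <- enrichment_1d(x, ann)
  expect_equal(r$score_x, r$score_y)
  expect_equal(r$score_x, r1$score, tolerance = 1e-12)
  # members top-ranked in both dimensions -> (1, 1)
  top <- ids[order(x, decreasing = TRUE)][1:12]
  ann_top <- annotation_collection(list(
    T = list(label = "t", category = "c", members = top)))
  rt <- enrichment_2d(x, x, ann_top, n_permutations = 200)
  expect_equal(c(rt$score_x, rt$score_y), c(1, 1))
  expect_lt(rt$p, 0.05)
})

test_that("signature scoring over time recovers an injected day-14 dip", {
  cfg <- generator_config(n_proteins = 600, seed = 17,
                          effect_config = list(frac_abundance_changed = 0))
  sim <- generate_timecourse_dataset(cfg)
  tab <- sim$table
  # deplete a 30-protein signature at day 14 only (AEC1-style injury dip)
  sig <- sim$truth$protein_id[1:30]
  j <- which(tab$samples$timepoint_days %in% 14)
  tab$values[1:30, j] <- tab$values[1:30, j] * 2^-2
  r <- compute_ratios(tab, imputation_params(seed = 7))
  ann <- annotation_collection(list(
    SIG = list(label = "aec1-like", category = "signature", members = sig)))
  res <- signature_timecourse(r, ann, ids = sim$truth$protein_id)
  d14 <- res[res$timepoint_days == 14, ]
  expect_lt(d14$score, 0)
  expect_true(d14$significant)
  # null time points stay (essentially) unflagged at alpha = 0.05
  expect_lte(sum(res$significant[res$timepoint_days != 14]), 1)
})
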