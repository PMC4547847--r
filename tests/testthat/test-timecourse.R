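test_that("downshifted-normal imputation reproduces its target moments", {
  set.seed(1)
  ref <- rnorm(5000, 25, 2)
  mu <- mean(ref); sigma <- sd(ref)
  vals <- c(rep(NA_real_, 1e5), ref)
  out <- impute_missing(vals, imputation_params(seed = 99),
                        reference_distribution = ref)
  draws <- out[1:1e5]
  expect_lt(abs(mean(draws) - (mu - 1.8 * sigma)), 0.01 * sigma)
  expect_lt(abs(sd(draws) - 0.3 * sigma), 0.01 * sigma)
  # imputed values sit below the reference mean (1e-6 quantile margin)
  expect_lt(max(draws), mu - 1.8 * sigma + qnorm(1 - 1e-6) * 0.3 * sigma)
  # determinism and no-op behavior
  out2 <- impute_missing(vals, imputation_params(seed = 99),
                         reference_distribution = ref)
  expect_identical(out, out2)
  full <- impute_missing(ref, imputation_params(seed = 1))
  expect_equal(as.numeric(full), ref)
  expect_error(impute_missing(c(NA, 1:40 * 0 + 5),
                              reference_distribution = rep(5, 40)),
               "degenerate")
  expect_error(impute_missing(c(NA, rnorm(10)),
                              reference_distribution = rnorm(10)), ">=30")
})

test_that("ratio computation follows the validity and imputation rules", {
  # 4 PBS + 2 treated columns, one protein per rule case
  filler <- matrix(rep(2, 36), 6)  # log2 reference mass for the imputer
  vals <- 2^rbind(
    c(1, 1, 1, 1, 3, 3),          # fully measured
    c(1, 1, NA, NA, 3, 3),        # control 50% valid -> denominator imputed
    c(1, 1, 1, 1, NA, NA),        # treated empty -> numerator imputed
    c(1, NA, NA, NA, NA, NA),     # control 25% valid + treated empty -> rule
    c(NA, NA, NA, NA, 3, 3),      # control empty, treated measured -> rule
    filler + matrix(rnorm(36, 0, 0.1), 6))
  tab <- make_table(vals, condition = c(rep("PBS", 4), "BLEO", "BLEO"),
                    timepoint_days = c(rep(NA, 4), 14, 14))
  r <- compute_ratios(tab, imputation_params(seed = 2))
  expect_equal(unname(r$log2_ratio[1, ]), c(2, 2))
  expect_equal(unname(r$provenance[1, ]), c("MEASURED", "MEASURED"))
  expect_equal(unname(r$provenance[2, ]), c("IMPUTED_DEN", "IMPUTED_DEN"))
  expect_equal(unname(r$provenance[3, ]), c("IMPUTED_NUM", "IMPUTED_NUM"))
  expect_equal(unname(r$provenance[4, ]), c("MISSING_RULE", "MISSING_RULE"))
  expect_true(all(is.na(r$log2_ratio[4, ])))
  expect_equal(unname(r$provenance[5, ]), c("MISSING_RULE", "MISSING_RULE"))
  # IMPUTED_DEN implies the control had >=50% valid values
  expect_gte(r$control_valid_fraction[2], 0.5)
})

test_that("even-count control median is the mean of the middle pair", {
  vals <- 2^rbind(c(log2(2), log2(4), log2(8), log2(16), log2(12)))
  tab <- make_table(vals, condition = c(rep("PBS", 4), "BLEO"),
                    timepoint_days = c(rep(NA, 4), 14))
  r <- compute_ratios(tab)
  expect_equal(unname(2^r$denominator_log2[1]), sqrt(4 * 8), tolerance = 1e-12)
  # treated 8 over PBS median 2
  vals2 <- 2^rbind(c(1, 1, 1, 1, 3))
  tab2 <- make_table(vals2, condition = c(rep("PBS", 4), "BLEO"),
                     timepoint_days = c(rep(NA, 4), 14))
  expect_equal(unname(compute_ratios(tab2)$log2_ratio[1, 1]), 2)
})

test_that("time-course ANOVA agrees with the explicit SS oracle", {
  groups <- rep(c(3, 14, 28, 56), times = c(3, 7, 4, 3))
  set.seed(51)
  for (i in 1:100) {
    y <- rnorm(length(groups)) + rep(rnorm(4, sd = 0.7),
                                     times = c(3, 7, 4, 3))
    res <- qdspr:::row_oneway(matrix(y, 1), groups)
    o <- oracle_oneway(y, groups)
    expect_equal(res$F, o$F, tolerance = 1e-10)
    expect_equal(res$p, o$p, tolerance = 1e-10)
    # and against stats::aov as a second, independent route
    av <- summary(aov(y ~ factor(groups)))[[1]]
    expect_equal(res$F, av$`F value`[1], tolerance = 1e-8)
  }
  # all equal values: F = 0, p = 1
  res0 <- qdspr:::row_oneway(matrix(rep(2, 17), 1), groups)
  expect_equal(res0$p, 1)
  expect_equal(res0$F, 0)
})

test_that("compliance regression matches closed-form OLS and cor.test", {
  x <- c(0.2, 0.5, 0.8, 1.0, 1.3)
  y <- 2 * x + 1
  res <- compliance_regression(matrix(y, 1), compliance_ratio = x)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)
  # constant response is untested
  resc <- compliance_regression(matrix(rep(1, 5), 1), compliance_ratio = x)
  expect_false(resc$tested)
  # noisy simulated mice against lm / cor.test
  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    xs <- runif(n, 0.3, 1.5)
    ys <- -0.8 * xs + rnorm(n, 0, 0.5)
    res2 <- compliance_regression(matrix(ys, 1), compliance_ratio = xs)
    fit <- lm(ys ~ xs)
    ct <- cor.test(xs, ys)
    expect_equal(res2$slope, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(res2$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(res2$pearson_r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res2$p, ct$p.value, tolerance = 1e-10)
    expect_equal(sign(res2$slope), sign(res2$pearson_r))
  }
  # 30 mice, slope -0.8: estimate within the OLS 95% CI
  set.seed(62)
  xs <- runif(30, 0.3, 1.5)
  ys <- -0.8 * xs + rnorm(30, 0, 0.5)
  res3 <- compliance_regression(matrix(ys, 1), compliance_ratio = xs)
  ci <- confint(lm(ys ~ xs))[2, ]
  expect_gte(-0.8, ci[1])
  expect_lte(-0.8, ci[2])
  expect_gte(res3$slope, ci[1])
  expect_lte(res3$slope, ci[2])
})

test_that("null time course centres measured ratios at zero", {
  cfg <- generator_config(n_proteins = 1000, seed = 14,
                          effect_config = list(frac_abundance_changed = 0))
  sim <- generate_timecourse_dataset(cfg)
  r <- compute_ratios(sim$table, imputation_params(seed = 3))
  measured <- r$log2_ratio[r$provenance == "MEASURED"]
  expect_lt(abs(median(measured)), 0.02)
})
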