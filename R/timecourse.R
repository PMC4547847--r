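# Ratiometric time-course analysis with left-censored imputation.
#
# Label-free non-detections are missing-not-at-random (low intensities fall
# below the detection limit), so missing values are drawn from a normal
# distribution downshifted from the observed intensity distribution:
# N(mu - downshift*sigma, (width*sigma)^2) with defaults 1.8 and 0.3 sigma.

#' Imputation parameters for left-censored missing values
#'
#' @param downshift location shift in reference-sd units, default 1.8.
#' @param width sd of the imputation distribution in reference-sd units,
#'   default 0.3.
#' @param seed RNG seed making the draws reproducible.
#' @param reference `"GLOBAL"`: moments taken from all observed log2 values
#'   pooled (default); `"PER_SAMPLE"`: per-column moments.
#' @return list of class `imputation_params`.
#' @export
imputation_params <- function(downshift = 1.8, width = 0.3, seed = 1,
                              reference = c("GLOBAL", "PER_SAMPLE")) {
  stopifnot(downshift >= 0, width > 0)
  structure(list(downshift = downshift, width = width, seed = seed,
                 reference = match.arg(reference)),
            class = "imputation_params")
}

#' Downshifted-normal imputation
#'
#' Replaces each `NA` in `values` with an independent draw from
#' `N(mu - downshift*sigma, (width*sigma)^2)`, where `mu` and `sigma` are the
#' mean and sd of the reference distribution (all observed log2 intensities).
#' Draw order is fixed by position (column-major), so results are
#' reproducible under a fixed seed.
#'
#' @param values numeric vector or matrix (log2 scale) with `NA` for missing.
#' @param params an [imputation_params()].
#' @param reference_distribution numeric vector the moments are estimated
#'   from; defaults to the non-missing entries of `values`.
#' @return object of the same shape with `NA` filled in; attribute `imputed`
#'   marks the filled positions.
#' @export
impute_missing <- function(values, params = imputation_params(),
                           reference_distribution = NULL) {
  ref <- reference_distribution %||% values[!is.na(values)]
  ref <- ref[is.finite(ref)]
  if (length(ref) < 30)
    stop("reference distribution needs >=30 values, got ", length(ref))
  mu <- mean(ref); sigma <- stats::sd(ref)
  if (sigma == 0) stop("degenerate reference distribution (sd = 0)")
  idx <- which(is.na(values))
  out <- values
  if (length(idx)) {
    set.seed(params$seed)
    out[idx] <- stats::rnorm(length(idx),
                             mean = mu - params$downshift * sigma,
                             sd = params$width * sigma)
  }
  attr(out, "imputed") <- idx
  out
}

RATIO_PROVENANCE <- c("MEASURED", "IMPUTED_NUM", "IMPUTED_DEN", "MISSING_RULE")

#' Ratios of treated replicates to the control median
#'
#' For each protein, time point and treated replicate, computes the log2
#' ratio of the replicate's intensity to the median intensity of the control
#' (PBS) samples, applying the study's validity rules:
#' \itemize{
#'   \item numerator: the measured value when present; when a treated time
#'     point has no valid value at all, its replicates are imputed — but only
#'     if the control has at least 50\% valid values; otherwise the cells are
#'     `MISSING_RULE`. A missing replicate inside a partially valid time
#'     point stays missing (`MISSING_RULE`), matching a median-level reading
#'     of the validity rule.
#'   \item denominator: the median of the control values; when the control is
#'     partially missing but >=50\% valid, the missing control replicates are
#'     imputed before taking the median (`IMPUTED_DEN`); a control with <50\%
#'     valid values contributes its valid-value median when the numerator is
#'     measured, and blocks imputation otherwise.
#' }
#'
#' @param table an [intensity_table()] containing PBS controls and treated
#'   samples (one sample per mouse).
#' @param params an [imputation_params()].
#' @param control condition label of the controls, default `"PBS"`.
#' @param denominator `"median"` (default) or `"mean"` of the control values
#'   (the BALF analysis pools controls by the mean).
#' @return list of class `ratio_matrix`: `log2_ratio` (proteins x treated
#'   samples), `provenance` (same shape, values of `RATIO_PROVENANCE`),
#'   `samples` (design rows of the treated columns), `denominator_log2`.
#' @export
compute_ratios <- function(table, params = imputation_params(),
                           control = "PBS",
                           denominator = c("median", "mean")) {
  stopifnot(inherits(table, "IntensityTable"))
  denominator <- match.arg(denominator)
  s <- table$samples
  is_ctrl <- s$condition == control
  if (!any(is_ctrl)) stop("no control ('", control, "') samples in table")
  if (all(is_ctrl)) stop("no treated samples in table")
  lm2 <- log2_matrix(table)
  ctrl_mat <- lm2[, is_ctrl, drop = FALSE]
  trt_mat <- lm2[, !is_ctrl, drop = FALSE]
  trt_samples <- s[!is_ctrl, , drop = FALSE]
  n <- nrow(lm2)

  ctrl_valid <- rowSums(!is.na(ctrl_mat))
  ctrl_frac <- ctrl_valid / ncol(ctrl_mat)

  # reference distribution for imputation: all observed log2 intensities
  # (its adequacy is only enforced when a draw is actually needed)
  ref <- lm2[is.finite(lm2)]
  mu <- mean(ref); sigma <- stats::sd(ref)
  set.seed(params$seed)
  draw <- function(k) {
    if (length(ref) < 30)
      stop("too few observed values for imputation (need >=30, have ",
           length(ref), ")")
    if (is.na(sigma) || sigma == 0)
      stop("degenerate reference distribution (sd = 0)")
    stats::rnorm(k, mu - params$downshift * sigma, params$width * sigma)
  }

  # denominator: impute minority-missing control cells where >=50% valid
  ctrl_imp <- ctrl_mat
  den_imputed <- rep(FALSE, n)
  need <- which(ctrl_frac >= 0.5 & ctrl_frac < 1)
  for (i in need) {
    miss <- which(is.na(ctrl_mat[i, ]))
    ctrl_imp[i, miss] <- draw(length(miss))
    den_imputed[i] <- TRUE
  }
  agg <- if (denominator == "median") {
    apply(ctrl_imp, 1, stats::median, na.rm = TRUE)
  } else {
    rowMeans(ctrl_imp, na.rm = TRUE)
  }
  agg[ctrl_valid == 0] <- NA_real_

  tp <- trt_samples$timepoint_days
  ratio <- matrix(NA_real_, n, ncol(trt_mat),
                  dimnames = dimnames(trt_mat))
  prov <- matrix("MISSING_RULE", n, ncol(trt_mat),
                 dimnames = dimnames(trt_mat))
  for (d in unique(tp)) {
    j <- if (is.na(d)) which(is.na(tp)) else which(!is.na(tp) & tp == d)
    sub <- trt_mat[, j, drop = FALSE]
    group_valid <- rowSums(!is.na(sub))
    # measured numerators (need a usable denominator)
    meas <- !is.na(sub) & !is.na(agg)
    ratio[, j][meas] <- (sub - agg)[meas]
    prov[, j][meas] <- ifelse(den_imputed[row(sub)[meas]],
                              "IMPUTED_DEN", "MEASURED")
    # treated time point entirely missing: impute only if control >=50% valid
    imp_rows <- which(group_valid == 0 & ctrl_frac >= 0.5)
    if (length(imp_rows)) {
      num <- matrix(draw(length(imp_rows) * length(j)), length(imp_rows))
      ratio[imp_rows, j] <- num - agg[imp_rows]
      prov[imp_rows, j] <- "IMPUTED_NUM"
    }
  }
  structure(list(log2_ratio = ratio, provenance = prov,
                 samples = trt_samples, denominator_log2 = agg,
                 control_valid_fraction = ctrl_frac),
            class = "ratio_matrix")
}

#' One-way ANOVA of log2 ratios over time
#'
#' Tests, per protein, whether the log2 ratio changes across time points
#' (fixed-effects one-way ANOVA), with Benjamini-Hochberg correction over all
#' tested proteins. A protein is tested when at least two time points carry
#' at least two valid ratios.
#'
#' @param ratios a `ratio_matrix` from [compute_ratios()].
#' @return data.frame: `protein_id`, `F`, `df1`, `df2`, `p`, `q`, `tested`.
#' @export
anova_timecourse <- function(ratios) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  res <- row_oneway(ratios$log2_ratio, ratios$samples$timepoint_days)
  data.frame(protein_id = rownames(ratios$log2_ratio),
             F = res$F, df1 = res$df1, df2 = res$df2, p = res$p,
             q = bh_fdr(res$p), tested = res$tested,
             stringsAsFactors = FALSE)
}

#' Protein-abundance versus lung-compliance regression
#'
#' Per protein, ordinary least squares of the log2 ratio on the per-mouse
#' compliance ratio, plus the Pearson correlation with its two-sided t-based
#' p-value on n-2 degrees of freedom and BH correction across proteins. The
#' compliance ratio is each mouse's compliance divided by the median control
#' compliance.
#'
#' @param ratios a `ratio_matrix` whose columns are per-mouse samples with a
#'   `compliance` design column, or a plain proteins x mice matrix (then give
#'   `compliance_ratio`).
#' @param compliance_ratio optional numeric vector over columns, overriding
#'   the design-derived ratio.
#' @param control_compliance compliance values of the control mice used for
#'   the ratio denominator (required when the design lacks controls).
#' @return data.frame: `protein_id`, `slope`, `intercept`, `pearson_r`, `n`,
#'   `p`, `q`, `tested`.
#' @export
compliance_regression <- function(ratios, compliance_ratio = NULL,
                                  control_compliance = NULL) {
  if (inherits(ratios, "ratio_matrix")) {
    y <- ratios$log2_ratio
    if (is.null(compliance_ratio)) {
      comp <- ratios$samples$compliance
      den <- stats::median(control_compliance %||% comp, na.rm = TRUE)
      compliance_ratio <- comp / den
    }
  } else {
    y <- as.matrix(ratios)
    if (is.null(compliance_ratio))
      stop("compliance_ratio required for a plain matrix")
  }
  res <- row_ols(y, compliance_ratio)
  data.frame(protein_id = rownames(y) %||% seq_len(nrow(y)),
             slope = res$slope, intercept = res$intercept,
             pearson_r = res$pearson_r, n = res$n, p = res$p,
             q = bh_fdr(res$p), tested = res$tested,
             stringsAsFactors = FALSE)
}
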