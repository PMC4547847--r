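# Annotation enrichment: Fisher's exact test on categorical membership, and
# rank-based 1D/2D enrichment with the bounded score
#   score = 2*U / (n_in * n_out) - 1
# (rank-biserial correlation of the Mann-Whitney U), positive when term
# members carry high values.

match_members <- function(values, annotations) {
  ids <- names(values)
  if (is.null(ids)) stop("'values' must be named by gene/protein id")
  lapply(annotations, function(t) which(ids %in% t$members))
}

#' Fisher's exact test per annotation term
#'
#' Tests over-/under-representation of each term in a foreground set against
#' a background, two-sided, with BH correction across terms.
#'
#' @param foreground character vector of ids (subset of `background`).
#' @param background character vector of all tested ids.
#' @param annotations an `AnnotationCollection`.
#' @return data.frame: `term_id`, `label`, `fg_in`, `fg_out`, `bg_in`,
#'   `bg_out`, `odds_ratio`, `p`, `q` (terms with no background overlap are
#'   skipped).
#' @export
fisher_enrichment <- function(foreground, background, annotations) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!length(foreground)) stop("empty foreground")
  if (length(background) < 2) stop("background needs >=2 ids")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  rows <- lapply(names(annotations), function(id) {
    members <- annotations[[id]]$members
    in_bg <- background %in% members
    if (!any(in_bg)) return(NULL)
    in_fg <- background %in% foreground
    tab <- matrix(c(sum(in_fg & in_bg), sum(in_fg & !in_bg),
                    sum(!in_fg & in_bg), sum(!in_fg & !in_bg)),
                  2, 2, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(term_id = id, label = annotations[[id]]$label,
               fg_in = tab[1, 1], fg_out = tab[1, 2],
               bg_in = tab[2, 1], bg_out = tab[2, 2],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the background")
  out$q <- bh_fdr(out$p)
  out
}

# core 1D machinery on a prepared rank vector; returns U, score and the
# tie-corrected normal p (exact via pwilcox when tie-free and small)
rank_enrichment_core <- function(ranks, member_idx, n_total, tie_table,
                                 exact_limit = 10000) {
  n_in <- length(member_idx)
  n_out <- n_total - n_in
  U <- sum(ranks[member_idx]) - n_in * (n_in + 1) / 2
  # (2U - n1n2)/n1n2 rather than 2U/n1n2 - 1: the numerator is exact, making
  # complement antisymmetry hold to the last bit
  score <- (2 * U - n_in * n_out) / (n_in * n_out)
  has_ties <- any(tie_table > 1)
  if (!has_ties && n_in * n_out <= exact_limit) {
    # exact Mann-Whitney distribution (no ties)
    p_low <- stats::pwilcox(U, n_in, n_out)
    p_high <- stats::pwilcox(U - 1, n_in, n_out, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    mu <- n_in * n_out / 2
    tie_term <- sum(tie_table^3 - tie_table)
    sigma2 <- n_in * n_out / 12 *
      ((n_total + 1) - tie_term / (n_total * (n_total - 1)))
    if (sigma2 <= 0) return(list(U = U, score = 0, p = 1))
    # continuity-corrected normal approximation with an Edgeworth kurtosis
    # term (U is symmetric, so the skew term vanishes); the kurtosis of U is
    # gamma2 = -(6/5)(n1^2+n2^2+n1n2+n1+n2) / (n1 n2 (N+1))
    u_low <- min(U, n_in * n_out - U)
    z <- (u_low + 0.5 - mu) / sqrt(sigma2)
    gamma2 <- -(6 / 5) * (n_in^2 + n_out^2 + n_in * n_out + n_in + n_out) /
      (n_in * n_out * (n_total + 1))
    F_low <- stats::pnorm(z) -
      stats::dnorm(z) * (gamma2 / 24) * (z^3 - 3 * z)
    p <- min(1, max(0, 2 * F_low))
  }
  list(U = U, score = score, p = p)
}

#' 1D rank-based annotation enrichment
#'
#' For each term, ranks all scored ids (mid-ranks for ties) and computes the
#' Mann-Whitney U of members versus non-members; the normalized enrichment
#' score `2U/(n_in n_out) - 1` lies in `[-1, 1]` with +1 when members occupy
#' exactly the top ranks. P-values use the exact U distribution when the
#' term is small and the values tie-free, otherwise the tie-corrected normal
#' approximation; BH correction across terms.
#'
#' @param values named numeric vector of per-id scores (e.g. log2 ratios,
#'   insoluble shares).
#' @param annotations an `AnnotationCollection`.
#' @param min_members minimum scored members for a term to be tested,
#'   default 5.
#' @return data.frame: `term_id`, `label`, `n_members_tested`, `score`, `U`,
#'   `p`, `q`.
#' @export
enrichment_1d <- function(values, annotations, min_members = 5) {
  values <- values[is.finite(values)]
  n_total <- length(values)
  ranks <- rank(values, ties.method = "average")
  tie_table <- table(values)
  members <- match_members(values, annotations)
  rows <- lapply(names(annotations), function(id) {
    idx <- members[[id]]
    if (length(idx) < min_members || n_total - length(idx) < 1) return(NULL)
    core <- rank_enrichment_core(ranks, idx, n_total, tie_table)
    data.frame(term_id = id, label = annotations[[id]]$label,
               n_members_tested = length(idx), score = core$score,
               U = core$U, p = core$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term_id = character(0)))
  out$q <- bh_fdr(out$p)
  out
}

#' 2D rank-based annotation enrichment
#'
#' Computes the 1D enrichment score of each term separately in two data
#' dimensions (e.g. proteome and transcriptome log2 ratios) and a joint
#' p-value from a membership-permutation null of `max(|score_x|, |score_y|)`,
#' which detects both correlated and uncorrelated category shifts.
#'
#' @param values_x,values_y named numeric vectors over a shared id set.
#' @param annotations an `AnnotationCollection`.
#' @param min_members minimum scored members per term, default 5.
#' @param n_permutations membership permutations, default 10000.
#' @param seed RNG seed.
#' @return data.frame: `term_id`, `label`, `n_members_tested`, `score_x`,
#'   `score_y`, `p`, `q`.
#' @export
enrichment_2d <- function(values_x, values_y, annotations, min_members = 5,
                          n_permutations = 10000, seed = 1) {
  ids <- intersect(names(values_x)[is.finite(values_x)],
                   names(values_y)[is.finite(values_y)])
  if (!length(ids)) stop("no ids scored in both dimensions")
  vx <- values_x[ids]; vy <- values_y[ids]
  n_total <- length(ids)
  rx <- rank(vx, ties.method = "average")
  ry <- rank(vy, ties.method = "average")
  members <- match_members(vx, annotations)
  set.seed(seed)
  score_of <- function(r, idx, n_in, n_out) {
    U <- sum(r[idx]) - n_in * (n_in + 1) / 2
    (2 * U - n_in * n_out) / (n_in * n_out)
  }
  rows <- lapply(names(annotations), function(id) {
    idx <- members[[id]]
    n_in <- length(idx); n_out <- n_total - n_in
    if (n_in < min_members || n_out < 1) return(NULL)
    sx <- score_of(rx, idx, n_in, n_out)
    sy <- score_of(ry, idx, n_in, n_out)
    stat <- max(abs(sx), abs(sy))
    perm_idx <- matrix(NA_integer_, n_permutations, n_in)
    for (b in seq_len(n_permutations))
      perm_idx[b, ] <- sample.int(n_total, n_in)
    sx_null <- (2 * (matrix(rx[perm_idx], n_permutations) |> rowSums()
                     - n_in * (n_in + 1) / 2) / (n_in * n_out)) - 1
    sy_null <- (2 * (matrix(ry[perm_idx], n_permutations) |> rowSums()
                     - n_in * (n_in + 1) / 2) / (n_in * n_out)) - 1
    exceed <- sum(pmax(abs(sx_null), abs(sy_null)) >= stat - 1e-12)
    data.frame(term_id = id, label = annotations[[id]]$label,
               n_members_tested = n_in, score_x = sx, score_y = sy,
               p = (exceed + 1) / (n_permutations + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term_id = character(0)))
  out$q <- bh_fdr(out$p)
  out
}

#' Cell-type signature enrichment over the time course
#'
#' Summarizes each protein per time point by the median of its replicate
#' log2 ratios, then applies [enrichment_1d()] per time point; a signature x
#' time-point matrix of normalized scores with significance flags at the
#' configured alpha.
#'
#' @param ratios a `ratio_matrix` from [compute_ratios()].
#' @param signatures an `AnnotationCollection` keyed like the ratio row
#'   names (gene or protein ids; see `ids`).
#' @param ids per-protein ids matching the signature namespace; defaults to
#'   the ratio row names.
#' @param alpha significance level for the flag, default 0.05.
#' @param min_members minimum quantified members, default 5.
#' @return long data.frame: `term_id`, `label`, `timepoint_days`,
#'   `n_members_tested`, `score`, `p`, `q`, `significant`.
#' @export
signature_timecourse <- function(ratios, signatures, ids = NULL,
                                 alpha = 0.05, min_members = 5) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  ids <- ids %||% rownames(ratios$log2_ratio)
  tp <- ratios$samples$timepoint_days
  rows <- lapply(sort(unique(tp)), function(d) {
    j <- which(!is.na(tp) & tp == d)
    med <- apply(ratios$log2_ratio[, j, drop = FALSE], 1, stats::median,
                 na.rm = TRUE)
    names(med) <- ids
    res <- enrichment_1d(med, signatures, min_members = min_members)
    if (!nrow(res)) return(NULL)
    res$timepoint_days <- d
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term_id = character(0)))
  out$significant <- out$p < alpha
  out[, c("term_id", "label", "timepoint_days", "n_members_tested",
          "score", "U", "p", "q", "significant")]
}
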