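#' Generator configuration for the synthetic study designs
#'
#' Returns the default configuration of the synthetic-data generator. The
#' defaults encode the three study designs being emulated: QDSP (4 solubility
#' fractions x PBS/bleomycin x 4 replicates), a tissue time course (day 3
#' n=3, day 14 n=7, day 28 n=4, day 56 n=3 versus 16 PBS controls), and BALF
#' (4 mice per condition at 6 time points). Intensity scale, noise, effect
#' sizes and the logistic left-censoring curve are package choices documented
#' in the methods vignette.
#'
#' @param n_proteins number of simulated protein groups.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param ... overrides for any default element (partial lists are merged).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 5000, seed = 1, ...) {
  cfg <- list(
    n_proteins = n_proteins,
    seed = seed,
    class_proportions = c(CYTOSOLIC = 0.40, MEMBRANE = 0.20, NUCLEAR = 0.20,
                          CYTOSKELETAL = 0.10, ECM = 0.10),
    profile_templates = rbind(
      CYTOSOLIC    = c(0.70, 0.20, 0.07, 0.03),
      MEMBRANE     = c(0.10, 0.45, 0.35, 0.10),
      NUCLEAR      = c(0.15, 0.30, 0.40, 0.15),
      CYTOSKELETAL = c(0.05, 0.15, 0.30, 0.50),
      ECM          = c(0.02, 0.05, 0.13, 0.80)),
    abundance_log2_mean = 25,
    abundance_log2_sd = 2.5,
    replicate_cv = 0.2,
    missingness = list(midpoint_log2 = 15, slope = 0.8),
    effect_config = list(frac_abundance_changed = 0.10,
                         frac_profile_shifted = 0.10,
                         log2fc_sd = 1,
                         amplitude_shape = 2,     # gamma shape of |amplitude|
                         amplitude_mean = 1.5,    # gamma mean (log2 units)
                         shift_mass = 0.40),
    timecourse_design = list(treated_days = c(3, 14, 28, 56),
                             treated_n = c(3, 7, 4, 3),
                             n_controls = 16),
    balf_design = list(days = c(3, 7, 14, 21, 28, 56),
                       mice_per_condition = 4,
                       frac_elf = 0.15,
                       frac_plasma = 0.05,
                       elf_log2_mean = 3, elf_log2_sd = 1,
                       leakage_log2_mean = -3.3, leakage_log2_sd = 0.5,
                       plasma_spike_log2 = 2),
    burden_curve = c(`3` = 0.3, `14` = 1, `28` = 0.4, `56` = 0.1),
    burden_mouse_sd = 0.2,
    compliance_baseline = 1,
    compliance_noise_sd = 0.05,
    compliance_coupling = 0.7)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_proteins >= 1, cfg$replicate_cv >= 0)
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  sums <- rowSums(cfg$profile_templates)
  if (any(abs(sums - 1) > 1e-9))
    stop("every profile template must sum to 1: offending class(es) ",
         paste(rownames(cfg$profile_templates)[abs(sums - 1) > 1e-9],
               collapse = ", "))
  if (cfg$missingness$slope <= 0) stop("missingness slope must be positive")
  ec <- cfg$effect_config
  stopifnot(ec$frac_abundance_changed >= 0, ec$frac_abundance_changed <= 1,
            ec$frac_profile_shifted >= 0, ec$frac_profile_shifted <= 1,
            ec$shift_mass >= 0, ec$shift_mass <= 1)
  structure(cfg, class = "generator_config")
}

# log2-scale replicate noise sd implied by a multiplicative CV
log2_noise_sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)

# MNAR left-censoring: detection probability is logistic in log2 intensity
detect_prob <- function(log2_intensity, missingness) {
  stats::plogis(missingness$slope * (log2_intensity - missingness$midpoint_log2))
}

apply_missingness <- function(log2_mat, missingness) {
  p <- detect_prob(log2_mat, missingness)
  drop <- matrix(stats::runif(length(log2_mat)), nrow = nrow(log2_mat)) > p
  log2_mat[drop] <- NA_real_
  log2_mat
}

draw_protein_meta <- function(cfg) {
  n <- cfg$n_proteins
  cls <- sample(names(cfg$class_proportions), n, replace = TRUE,
                prob = cfg$class_proportions)
  data.frame(
    protein_id = sprintf("P%05d", seq_len(n)),
    gene_name = sprintf("Gene%05d", seq_len(n)),
    class = cls,
    base_log2 = stats::rnorm(n, cfg$abundance_log2_mean, cfg$abundance_log2_sd),
    stringsAsFactors = FALSE)
}

# signed effect amplitudes in log2 units; gamma-distributed magnitudes
draw_amplitudes <- function(n, ec, force_positive = FALSE) {
  mag <- stats::rgamma(n, shape = ec$amplitude_shape,
                       rate = ec$amplitude_shape / ec$amplitude_mean)
  sgn <- if (force_positive) rep(1, n) else sample(c(-1, 1), n, replace = TRUE)
  mag * sgn
}

#' Simulate a QDSP experiment with known ground truth
#'
#' Emulates quantitative detergent solubility profiling: every protein has a
#' class-specific expected distribution of its intensity mass over the four
#' solubility fractions (FR1, FR2, FR3, INSOL); bleomycin shifts the profile
#' of a configured fraction of proteins by convex mass transfer toward the
#' soluble or insoluble end, and changes total abundance for an independent
#' fraction. Replicate noise is multiplicative log-normal and non-detection
#' follows a logistic left-censoring curve in log2 intensity.
#'
#' @param config a [generator_config()].
#' @param n_replicates replicates per condition (default 4, as in the
#'   emulated design: PBS n=4 vs bleomycin day-14 n=4).
#' @return list with `table` (an [intensity_table()]) and `truth` (data.frame
#'   with `class`, `abundance_log2fc`, `profile_shifted`, `shift_direction`).
#' @export
generate_qdsp_dataset <- function(config = generator_config(),
                                  n_replicates = 4) {
  cfg <- validate_generator_config(config)
  set.seed(cfg$seed)
  meta <- draw_protein_meta(cfg)
  n <- cfg$n_proteins
  ec <- cfg$effect_config

  ab_changed <- stats::runif(n) < ec$frac_abundance_changed
  ab_lfc <- ifelse(ab_changed, stats::rnorm(n, 0, ec$log2fc_sd), 0)
  shifted <- stats::runif(n) < ec$frac_profile_shifted
  direction <- ifelse(shifted,
                      sample(c("TOWARD_INSOLUBLE", "TOWARD_SOLUBLE"), n,
                             replace = TRUE), NA_character_)

  tmpl <- cfg$profile_templates[meta$class, , drop = FALSE]
  tmpl_bleo <- tmpl
  m <- ec$shift_mass
  toward_ins <- which(shifted & direction == "TOWARD_INSOLUBLE")
  toward_sol <- which(shifted & direction == "TOWARD_SOLUBLE")
  e_ins <- c(0, 0, 0, 1); e_sol <- c(1, 0, 0, 0)
  if (length(toward_ins))
    tmpl_bleo[toward_ins, ] <- (1 - m) * tmpl[toward_ins, , drop = FALSE] +
      m * matrix(e_ins, length(toward_ins), 4, byrow = TRUE)
  if (length(toward_sol))
    tmpl_bleo[toward_sol, ] <- (1 - m) * tmpl[toward_sol, , drop = FALSE] +
      m * matrix(e_sol, length(toward_sol), 4, byrow = TRUE)

  fractions <- c("FR1", "FR2", "FR3", "INSOL")
  samples <- expand.grid(fraction = fractions,
                         replicate = seq_len(n_replicates),
                         condition = c("PBS", "BLEO"),
                         stringsAsFactors = FALSE)
  samples$timepoint_days <- ifelse(samples$condition == "BLEO", 14, NA_real_)
  samples$mouse_id <- sprintf("%s_m%d", samples$condition, samples$replicate)
  samples$compartment <- "TISSUE"
  samples$compliance <- NA_real_
  samples$sample_id <- sprintf("QDSP_%s_R%d_%s", samples$condition,
                               samples$replicate, samples$fraction)
  samples <- samples[, c("sample_id", "condition", "timepoint_days",
                         "fraction", "replicate", "mouse_id", "compartment",
                         "compliance")]

  s2 <- log2_noise_sd(cfg$replicate_cv)
  expected <- matrix(NA_real_, n, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    tm <- if (samples$condition[j] == "BLEO") tmpl_bleo else tmpl
    tot_log2 <- meta$base_log2 +
      if (samples$condition[j] == "BLEO") ab_lfc else 0
    expected[, j] <- tot_log2 + log2(tm[, match(samples$fraction[j], fractions)])
  }
  log2_obs <- expected +
    if (s2 > 0) matrix(stats::rnorm(length(expected), 0, s2), n) else 0
  log2_obs <- apply_missingness(log2_obs, cfg$missingness)

  proteins <- data.frame(protein_id = meta$protein_id,
                         gene_name = meta$gene_name,
                         stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = meta$protein_id,
                      gene_name = meta$gene_name,
                      class = meta$class,
                      base_log2 = meta$base_log2,
                      abundance_changed = ab_changed,
                      abundance_log2fc = ab_lfc,
                      profile_shifted = shifted,
                      shift_direction = direction,
                      stringsAsFactors = FALSE)
  list(table = intensity_table(2^log2_obs, proteins, samples), truth = truth,
       config = cfg)
}

timecourse_curves <- function(days) {
  rbind(EARLY    = stats::approx(c(0, 3, 14, 28, 56), c(0.8, 1, 0.3, 0.1, 0),
                                 xout = days, rule = 2)$y,
        FIBROTIC = stats::approx(c(0, 3, 14, 28, 56), c(0, 0.3, 1, 0.4, 0.1),
                                 xout = days, rule = 2)$y,
        LATE     = stats::approx(c(0, 3, 14, 28, 56), c(0, 0, 0.25, 0.6, 1),
                                 xout = days, rule = 2)$y)
}

#' Simulate the tissue injury-repair time course with compliance
#'
#' Emulates a bleomycin tissue time course: treated mice at day 3/14/28/56
#' (n = 3/7/4/3) against 16 PBS controls, one total-proteome sample per
#' mouse. Changed proteins follow temporal archetypes (inflammatory
#' early-peak, fibrotic day-14 peak, late resolution); each treated mouse
#' carries a latent fibrosis burden peaking at day 14, fibrotic-archetype
#' proteins scale with that burden, and lung compliance decays exponentially
#' in the burden — inducing protein-compliance correlations with known sign.
#'
#' @param config a [generator_config()].
#' @return list with `table`, `truth` (protein-level: archetype, amplitude,
#'   `true_log2fc_d<day>` columns) and `mice` (per-mouse burden and
#'   compliance).
#' @export
generate_timecourse_dataset <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  set.seed(cfg$seed + 1L)
  meta <- draw_protein_meta(cfg)
  n <- cfg$n_proteins
  ec <- cfg$effect_config
  des <- cfg$timecourse_design

  changed <- stats::runif(n) < ec$frac_abundance_changed
  archetype <- rep(NA_character_, n)
  archetype[changed] <- sample(c("EARLY", "FIBROTIC", "LATE"), sum(changed),
                               replace = TRUE, prob = c(0.3, 0.4, 0.3))
  amplitude <- rep(0, n)
  fib <- which(archetype == "FIBROTIC")
  oth <- which(changed & archetype != "FIBROTIC")
  # fibrosis proteins accumulate with burden, hence positive amplitudes
  amplitude[fib] <- draw_amplitudes(length(fib), ec, force_positive = TRUE)
  amplitude[oth] <- draw_amplitudes(length(oth), ec)

  mice <- rbind(
    data.frame(condition = "PBS", timepoint_days = NA_real_,
               mouse_id = sprintf("PBS_m%02d", seq_len(des$n_controls))),
    do.call(rbind, lapply(seq_along(des$treated_days), function(i)
      data.frame(condition = "BLEO", timepoint_days = des$treated_days[i],
                 mouse_id = sprintf("BLEO_d%02d_m%d", des$treated_days[i],
                                    seq_len(des$treated_n[i]))))))
  nm <- nrow(mice)
  curve_b <- cfg$burden_curve[as.character(mice$timepoint_days)]
  curve_b[is.na(curve_b)] <- 0
  mice$burden <- unname(curve_b *
    exp(stats::rnorm(nm, 0, cfg$burden_mouse_sd)))
  mice$burden[mice$condition == "PBS"] <- 0
  mice$compliance <- cfg$compliance_baseline *
    exp(-cfg$compliance_coupling * mice$burden +
          stats::rnorm(nm, 0, cfg$compliance_noise_sd))

  curves <- timecourse_curves(des$treated_days)
  true_lfc <- matrix(0, n, length(des$treated_days),
                     dimnames = list(meta$protein_id,
                                     paste0("true_log2fc_d", des$treated_days)))
  for (a in rownames(curves)) {
    idx <- which(archetype == a)
    true_lfc[idx, ] <- outer(amplitude[idx], curves[a, ])
  }

  s2 <- log2_noise_sd(cfg$replicate_cv)
  eff <- matrix(0, n, nm)
  treated <- which(mice$condition == "BLEO")
  for (j in treated) {
    d <- match(mice$timepoint_days[j], des$treated_days)
    e <- rep(0, n)
    e[oth] <- true_lfc[oth, d]
    # fibrotic proteins track the mouse's realized burden, not the day mean
    e[fib] <- amplitude[fib] * mice$burden[j]
    eff[, j] <- e
  }
  log2_obs <- meta$base_log2 + eff +
    if (s2 > 0) matrix(stats::rnorm(n * nm, 0, s2), n) else 0
  log2_obs <- apply_missingness(log2_obs, cfg$missingness)

  samples <- data.frame(sample_id = mice$mouse_id,
                        condition = mice$condition,
                        timepoint_days = mice$timepoint_days,
                        fraction = "TOTAL",
                        replicate = stats::ave(seq_len(nm),
                                               mice$condition,
                                               mice$timepoint_days,
                                               FUN = seq_along),
                        mouse_id = mice$mouse_id,
                        compartment = "TISSUE",
                        compliance = mice$compliance,
                        stringsAsFactors = FALSE)
  truth <- cbind(data.frame(protein_id = meta$protein_id,
                            gene_name = meta$gene_name,
                            class = meta$class,
                            base_log2 = meta$base_log2,
                            changed = changed,
                            archetype = archetype,
                            amplitude = amplitude,
                            stringsAsFactors = FALSE),
                 as.data.frame(true_lfc, row.names = NULL))
  list(table = intensity_table(2^log2_obs,
                               data.frame(protein_id = meta$protein_id,
                                          gene_name = meta$gene_name,
                                          stringsAsFactors = FALSE),
                               samples),
       truth = truth, mice = mice, config = cfg)
}

#' Simulate paired BALF and tissue proteomes
#'
#' Emulates bronchoalveolar lavage fluid sampled alongside tissue over six
#' time points in both conditions (4 mice per condition and time point).
#' Expected BALF intensity is `elf_weight * secretion + leakage_weight *
#' tissue`: epithelial-lining-fluid (ELF) members are secreted well above
#' their tissue level, non-members appear in BALF only as low-level leakage,
#' and plasma-like proteins gain an injury-dependent leakage spike. A
#' configured fraction of BALF proteins follows injury time-course
#' archetypes.
#'
#' @param config a [generator_config()].
#' @return list with `table` (BALF and TISSUE compartment samples), `truth`
#'   (per protein: `elf_member`, `plasma`, archetype/amplitude,
#'   `true_log2fc_d14` on BALF ratios).
#' @export
generate_balf_dataset <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  set.seed(cfg$seed + 2L)
  meta <- draw_protein_meta(cfg)
  n <- cfg$n_proteins
  ec <- cfg$effect_config
  des <- cfg$balf_design

  elf <- stats::runif(n) < des$frac_elf
  plasma <- !elf & stats::runif(n) < des$frac_plasma
  balf_offset <- ifelse(elf,
                        stats::rnorm(n, des$elf_log2_mean, des$elf_log2_sd),
                        stats::rnorm(n, des$leakage_log2_mean,
                                     des$leakage_log2_sd))
  changed <- stats::runif(n) < ec$frac_abundance_changed
  archetype <- rep(NA_character_, n)
  archetype[changed] <- sample(c("EARLY", "FIBROTIC", "LATE"), sum(changed),
                               replace = TRUE, prob = c(0.3, 0.4, 0.3))
  amplitude <- rep(0, n)
  idx_ch <- which(changed)
  amplitude[idx_ch] <- draw_amplitudes(
    length(idx_ch), ec, force_positive = FALSE)
  idx_fib <- which(archetype == "FIBROTIC")
  amplitude[idx_fib] <- abs(amplitude[idx_fib])

  curves <- timecourse_curves(des$days)
  spike_curve <- stats::approx(c(0, 3, 14, 28, 56), c(0.3, 1, 0.8, 0.3, 0),
                               xout = des$days, rule = 2)$y

  grid <- expand.grid(replicate = seq_len(des$mice_per_condition),
                      timepoint_days = des$days,
                      condition = c("PBS", "BLEO"),
                      stringsAsFactors = FALSE)
  grid$mouse_id <- sprintf("%s_d%02d_m%d", grid$condition,
                           grid$timepoint_days, grid$replicate)
  samples <- do.call(rbind, lapply(c("BALF", "TISSUE"), function(cp) {
    s <- grid
    s$compartment <- cp
    s$fraction <- if (cp == "BALF") "BALF" else "TOTAL"
    s$sample_id <- sprintf("%s_%s", cp, s$mouse_id)
    s
  }))
  samples$compliance <- NA_real_
  samples <- samples[, c("sample_id", "condition", "timepoint_days",
                         "fraction", "replicate", "mouse_id", "compartment",
                         "compliance")]

  ns <- nrow(samples)
  eff <- matrix(0, n, ns)
  is_balf <- samples$compartment == "BALF"
  for (j in which(is_balf & samples$condition == "BLEO")) {
    d <- match(samples$timepoint_days[j], des$days)
    e <- rep(0, n)
    for (a in rownames(curves)) {
      idx <- which(archetype == a)
      e[idx] <- amplitude[idx] * curves[a, d]
    }
    e[plasma] <- e[plasma] + des$plasma_spike_log2 * spike_curve[d]
    eff[, j] <- e
  }
  base <- matrix(meta$base_log2, n, ns)
  base[, is_balf] <- base[, is_balf] + balf_offset

  s2 <- log2_noise_sd(cfg$replicate_cv)
  log2_obs <- base + eff +
    if (s2 > 0) matrix(stats::rnorm(n * ns, 0, s2), n) else 0
  log2_obs <- apply_missingness(log2_obs, cfg$missingness)

  d14 <- match(14, des$days)
  true_d14 <- rep(0, n)
  for (a in rownames(curves)) {
    idx <- which(archetype == a)
    true_d14[idx] <- amplitude[idx] * curves[a, d14]
  }
  true_d14[plasma] <- true_d14[plasma] + des$plasma_spike_log2 * spike_curve[d14]

  truth <- data.frame(protein_id = meta$protein_id,
                      gene_name = meta$gene_name,
                      class = meta$class,
                      base_log2 = meta$base_log2,
                      elf_member = elf,
                      plasma = plasma,
                      balf_log2_offset = balf_offset,
                      changed = changed,
                      archetype = archetype,
                      amplitude = amplitude,
                      true_log2fc_d14 = true_d14,
                      stringsAsFactors = FALSE)
  list(table = intensity_table(2^log2_obs,
                               data.frame(protein_id = meta$protein_id,
                                          gene_name = meta$gene_name,
                                          stringsAsFactors = FALSE),
                               samples),
       truth = truth, config = cfg)
}

#' Derive annotation terms from simulation ground truth
#'
#' Builds one gene-set term per protein class (and per temporal archetype /
#' ELF membership where present in the truth table), optionally corrupted by
#' swapping a fraction of members with random non-members — so enrichment
#' recovery can be tested under imperfect annotation.
#'
#' @param truth ground-truth data.frame from one of the generators.
#' @param noise_frac fraction of each term's members swapped out, in `[0, 1)`.
#' @param seed RNG seed for the swaps.
#' @return An `AnnotationCollection` keyed by gene name.
#' @export
generate_annotations <- function(truth, noise_frac = 0, seed = 1) {
  stopifnot(noise_frac >= 0, noise_frac < 1)
  set.seed(seed)
  all_genes <- truth$gene_name
  sets <- split(all_genes, truth$class)
  if ("archetype" %in% names(truth)) {
    arch <- truth$archetype
    sets <- c(sets, split(all_genes[!is.na(arch)], arch[!is.na(arch)]))
  }
  if ("elf_member" %in% names(truth) && any(truth$elf_member))
    sets$ELF <- all_genes[truth$elf_member]
  terms <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    n_swap <- floor(noise_frac * length(members))
    if (n_swap > 0) {
      out_pool <- setdiff(all_genes, members)
      drop <- sample(members, n_swap)
      add <- sample(out_pool, min(n_swap, length(out_pool)))
      members <- c(setdiff(members, drop), add)
    }
    list(label = nm, category = "simulated", members = members)
  })
  names(terms) <- names(sets)
  annotation_collection(terms)
}
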