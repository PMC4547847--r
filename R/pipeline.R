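# End-to-end orchestration over the synthetic designs: simulate -> QDSP /
# time course / BALF -> enrichment, with reproducibility metadata. A single
# top-level seed derives all stage seeds by fixed offsets.

#' Validate an experimental design
#'
#' Checks replicate counts, fraction completeness and condition presence for
#' one of the three supported designs. QDSP requires all four solubility
#' fractions for every biological replicate.
#'
#' @param samples data.frame of sample metadata (as in an
#'   [intensity_table()]).
#' @param mode `"QDSP"`, `"TIMECOURSE"` or `"BALF"`.
#' @return data.frame of violations (`check`, `detail`); zero rows when the
#'   design passes.
#' @export
validate_design <- function(samples, mode = c("QDSP", "TIMECOURSE", "BALF")) {
  mode <- match.arg(mode)
  v <- list()
  add <- function(check, detail) v[[length(v) + 1]] <<- data.frame(
    check = check, detail = detail, stringsAsFactors = FALSE)
  if (!nrow(samples)) {
    add("no samples", "sample list is empty")
    return(do.call(rbind, v))
  }
  if (length(unique(samples$condition)) < 2)
    add("conditions", "fewer than two conditions present")
  if (mode == "QDSP") {
    key <- split(samples$fraction,
                 paste(samples$condition, samples$mouse_id, sep = "/"))
    for (k in names(key)) {
      miss <- setdiff(QDSP_FRACTIONS, key[[k]])
      if (length(miss))
        add("fraction completeness",
            sprintf("replicate %s lacks fraction(s) %s", k,
                    paste(miss, collapse = ",")))
    }
  }
  if (mode == "TIMECOURSE") {
    treated <- samples[samples$condition != "PBS", , drop = FALSE]
    if (!nrow(treated)) add("treated samples", "no treated samples")
    tp <- table(treated$timepoint_days)
    if (any(tp < 2))
      add("replicate count",
          sprintf("time point(s) with <2 replicates: %s",
                  paste(names(tp)[tp < 2], collapse = ",")))
    if (sum(samples$condition == "PBS") < 2)
      add("controls", "fewer than two PBS controls")
  }
  if (mode == "BALF") {
    if (!any(samples$compartment == "BALF"))
      add("compartment", "no BALF samples")
    if (!any(samples$compartment == "TISSUE"))
      add("compartment", "no TISSUE samples")
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(check = character(0), detail = character(0))
  out
}

#' Default pipeline run configuration
#'
#' @param output_dir directory for result tables.
#' @param seed top-level seed; all stage seeds derive from it by fixed
#'   offsets.
#' @param fdr FDR threshold used by every stage, default 0.05.
#' @param n_proteins simulated proteins per design.
#' @param stages subset of `c("qdsp", "timecourse", "balf", "enrich")`.
#' @param generator list of [generator_config()] overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1, fdr = 0.05, n_proteins = 2000,
                       stages = c("qdsp", "timecourse", "balf", "enrich"),
                       generator = list()) {
  cfg <- list(output_dir = output_dir, seed = seed, fdr = fdr,
              n_proteins = n_proteins, stages = stages,
              generator = generator)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  allowed <- c("output_dir", "seed", "fdr", "n_proteins", "stages",
               "generator")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  for (req in c("output_dir", "seed"))
    if (is.null(cfg[[req]])) stop("run config lacks required key: ", req)
  if (!is.null(cfg$fdr) && (cfg$fdr <= 0 || cfg$fdr >= 1))
    stop("fdr must lie in (0, 1): offending key 'fdr'")
  bad <- setdiff(cfg$stages, c("qdsp", "timecourse", "balf", "enrich"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the requested designs with known ground truth and runs every
#' downstream stage, writing one TSV per result (each with a
#' reproducibility header) plus a JSON run-metadata sidecar and `run.log`.
#' Identical configuration and seed yield byte-identical outputs.
#'
#' @param config a [run_config()] (or a path to a YAML file with the same
#'   keys).
#' @return invisibly, a named list of the result data.frames; side effect:
#'   tables under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(paste0(format(Sys.time(), "[%H:%M:%S] "), msg), log_con)
    message(msg)
  }
  fdr <- cfg$fdr %||% 0.05
  gen_args <- utils::modifyList(list(n_proteins = cfg$n_proteins %||% 2000,
                                     seed = cfg$seed),
                                cfg$generator)
  gcfg <- do.call(generator_config, gen_args)
  meta <- list(seed = cfg$seed, fdr = fdr, n_proteins = gen_args$n_proteins)
  results <- list()
  emit <- function(df, name) {
    write_result_table(df, file.path(cfg$output_dir, paste0(name, ".tsv")),
                       meta = meta)
    results[[name]] <<- df
  }

  if ("qdsp" %in% cfg$stages) {
    say("stage qdsp: simulating %d proteins", gcfg$n_proteins)
    sim <- generate_qdsp_dataset(gcfg)
    viol <- validate_design(sim$table$samples, "QDSP")
    if (nrow(viol)) stop("QDSP design invalid: ", viol$detail[1])
    stats <- qdsp_stats(sim$table, fdr = fdr)
    emit(stats, "qdsp_stats")
    say("stage qdsp: %d/%d proteins tested, %d significant profiles",
        sum(stats$interaction_tested), nrow(stats),
        sum(stats$significant_profile))
    results$qdsp_truth <- sim$truth
    results$qdsp_table <- sim$table
  }
  if ("timecourse" %in% cfg$stages) {
    say("stage timecourse: simulating %d proteins", gcfg$n_proteins)
    sim <- generate_timecourse_dataset(gcfg)
    viol <- validate_design(sim$table$samples, "TIMECOURSE")
    if (nrow(viol)) stop("time-course design invalid: ", viol$detail[1])
    ratios <- compute_ratios(sim$table,
                             imputation_params(seed = cfg$seed + 10L))
    an <- anova_timecourse(ratios)
    emit(an, "timecourse_anova")
    comp <- compliance_regression(
      ratios,
      control_compliance =
        sim$mice$compliance[sim$mice$condition == "PBS"])
    emit(comp, "compliance")
    say("stage timecourse: %d ANOVA-significant, %d compliance-significant",
        sum(an$q < fdr, na.rm = TRUE), sum(comp$q < fdr, na.rm = TRUE))
    results$timecourse_truth <- sim$truth
    results$timecourse_ratios <- ratios
  }
  if ("balf" %in% cfg$stages) {
    say("stage balf: simulating %d proteins", gcfg$n_proteins)
    sim <- generate_balf_dataset(gcfg)
    viol <- validate_design(sim$table$samples, "BALF")
    if (nrow(viol)) stop("BALF design invalid: ", viol$detail[1])
    lm2 <- log2_matrix(sim$table)
    is_balf <- sim$table$samples$compartment == "BALF"
    scores <- sam_scores(lm2[, is_balf, drop = FALSE],
                         lm2[, !is_balf, drop = FALSE],
                         sam_params(seed = cfg$seed + 11L), fdr = fdr)
    emit(scores, "balf_scores")
    d14 <- balf_day14_ttest(sim$table)
    emit(d14, "balf_day14")
    bt <- balf_timecourse(sim$table,
                          imputation_params(seed = cfg$seed + 12L))
    emit(bt$anova, "balf_anova")
    say("stage balf: %d ELF-enriched at FDR %.2f",
        sum(scores$elf_enriched), fdr)
    results$balf_truth <- sim$truth
  }
  if ("enrich" %in% cfg$stages) {
    if (is.null(results$qdsp_truth))
      stop("enrich stage needs the qdsp stage")
    say("stage enrich: annotation recovery")
    ann <- generate_annotations(results$qdsp_truth, noise_frac = 0.1,
                                seed = cfg$seed + 13L)
    shares <- insoluble_share(results$qdsp_table)
    vals <- shares[, "BLEO"]
    names(vals) <- results$qdsp_truth$gene_name
    enr <- enrichment_1d(vals, ann)
    enr <- enr[order(enr$score, decreasing = TRUE), ]
    emit(enr, "enrichment")
    say("stage enrich: top term by insoluble-share enrichment: %s",
        enr$term_id[1])
  }
  jsonlite::write_json(
    list(tool = paste0("qdspr ",
                       as.character(utils::packageVersion("qdspr"))),
         config = unclass(cfg),
         generator = lapply(unclass(gcfg), function(x)
           if (is.matrix(x)) as.data.frame(x) else x)),
    file.path(cfg$output_dir, "run_metadata.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
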