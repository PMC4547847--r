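#' Intensity table container
#'
#' An `IntensityTable` holds a proteins x samples matrix of *linear* MS
#' intensities together with per-protein metadata and the per-sample design.
#' Missing values are stored as `NA`; zeros are never stored (label-free
#' quantification software writes 0 as a non-detection sentinel, so zeros are
#' converted to `NA` on read).
#'
#' @param values numeric matrix, proteins x samples, strictly positive or
#'   `NA`. Row names are protein ids, column names sample ids.
#' @param proteins data.frame of protein metadata with at least `protein_id`
#'   and `gene_name`; optional `sequence`, `n_theoretical_peptides`,
#'   `is_contaminant`, `is_reverse`.
#' @param samples data.frame of sample metadata (`sample_id`, `condition`,
#'   `timepoint_days`, `fraction`, `replicate`, `mouse_id`, `compartment`,
#'   `compliance`).
#' @return An object of class `IntensityTable`.
#' @export
intensity_table <- function(values, proteins, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(proteins))
    stop("'proteins' must contain a 'protein_id' column")
  if (!"sample_id" %in% names(samples))
    stop("'samples' must contain a 'sample_id' column")
  if (nrow(values) != nrow(proteins))
    stop("row count of 'values' does not match 'proteins'")
  if (ncol(values) != nrow(samples))
    stop("column count of 'values' does not match 'samples'")
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (any(values <= 0, na.rm = TRUE))
    stop("intensities must be positive; encode non-detections as NA")
  samples$fraction <- check_fraction(samples$fraction)
  rownames(values) <- proteins$protein_id
  colnames(values) <- samples$sample_id
  rownames(proteins) <- NULL
  rownames(samples) <- NULL
  structure(list(values = values, proteins = proteins, samples = samples),
            class = "IntensityTable")
}

FRACTION_LEVELS <- c("FR1", "FR2", "FR3", "INSOL", "TOTAL", "BALF")

check_fraction <- function(x) {
  if (is.null(x)) return(rep(NA_character_, 0L))
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% FRACTION_LEVELS
  if (any(bad))
    stop("unknown fraction label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected ", paste(FRACTION_LEVELS, collapse = ", "), ")")
  x
}

#' @export
print.IntensityTable <- function(x, ...) {
  cat(sprintf("IntensityTable: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$values))))
  cond <- table(x$samples$condition, useNA = "ifany")
  cat("  samples by condition: ",
      paste(sprintf("%s=%d", names(cond), cond), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.IntensityTable <- function(x) dim(x$values)

#' Subset an intensity table by sample
#'
#' @param table an [intensity_table()].
#' @param idx logical or integer index over samples.
#' @return An `IntensityTable` restricted to the selected samples.
#' @export
subset_samples <- function(table, idx) {
  stopifnot(inherits(table, "IntensityTable"))
  intensity_table(table$values[, idx, drop = FALSE],
                  table$proteins,
                  table$samples[idx, , drop = FALSE])
}

#' Log2-transform the intensity matrix
#'
#' @param table an [intensity_table()].
#' @return numeric matrix of log2 intensities (`NA` preserved).
#' @export
log2_matrix <- function(table) {
  stopifnot(inherits(table, "IntensityTable"))
  log2(table$values)
}
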