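#' Read a proteinGroups-style intensity table
#'
#' Parses the wide tab-separated protein table emitted by common label-free
#' quantification software ("proteinGroups" dialect) together with a sample
#' sheet mapping intensity columns to the experimental design. Decoy
#' ("Reverse") and contaminant-flagged rows are removed and counted; zero or
#' blank intensities become `NA` (non-detections).
#'
#' @param path path to the tab-separated protein table. Recognized columns:
#'   `Majority protein IDs`, `Gene names`, `Sequence` (optional), `Reverse`,
#'   `Potential contaminant`, and per-sample intensity columns named in the
#'   sample sheet.
#' @param sample_sheet path to a tab-separated sample sheet (or a YAML file
#'   with one record per sample) with columns `sample_id`, `column` (the
#'   intensity column name in `path`), `condition`, and optionally
#'   `timepoint_days`, `fraction`, `replicate`, `mouse_id`, `compartment`,
#'   `compliance`.
#' @param intensity_prefix prefix tried when `column` entries are bare sample
#'   names, default `"Intensity "`.
#' @return An [intensity_table()]; attribute `filter_counts` records the
#'   number of reverse/contaminant rows removed.
#' @export
read_protein_groups <- function(path, sample_sheet,
                                intensity_prefix = "Intensity ") {
  raw <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  sheet <- read_sample_sheet(sample_sheet)

  cols <- sheet$column
  if (is.null(cols)) cols <- paste0(intensity_prefix, sheet$sample_id)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("sample sheet maps column(s) absent from the protein table: ",
         paste(missing_cols, collapse = ", "))

  flag_col <- function(nm) {
    if (nm %in% names(raw)) !is.na(raw[[nm]]) & raw[[nm]] == "+"
    else rep(FALSE, nrow(raw))
  }
  is_rev <- flag_col("Reverse")
  is_con <- flag_col("Potential contaminant")
  keep <- !(is_rev | is_con)
  filter_counts <- c(reverse = sum(is_rev), contaminant = sum(is_con & !is_rev))
  raw <- raw[keep, , drop = FALSE]

  pick <- function(nm, default = NA) {
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  protein_id <- as.character(pick("Majority protein IDs"))
  if (all(is.na(protein_id))) stop("no 'Majority protein IDs' column found")
  if (anyDuplicated(protein_id))
    stop("duplicate protein_id in ", path, ": ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))

  values <- as.matrix(raw[, cols, drop = FALSE])
  storage.mode(values) <- "double"
  values[!is.finite(values) | values <= 0] <- NA_real_

  seqs <- as.character(pick("Sequence", NA_character_))
  n_pep <- suppressWarnings(as.integer(pick("Number of theoretical peptides")))
  proteins <- data.frame(
    protein_id = protein_id,
    gene_name = as.character(pick("Gene names", NA_character_)),
    sequence = seqs,
    n_theoretical_peptides = n_pep,
    stringsAsFactors = FALSE)

  out <- intensity_table(values, proteins,
                         sheet[, setdiff(names(sheet), "column"), drop = FALSE])
  attr(out, "filter_counts") <- filter_counts
  out
}

#' Read a sample sheet
#'
#' @param path tab-separated file (or `.yml`/`.yaml` with a list of records)
#'   describing one sample per row.
#' @return data.frame with canonical column types.
#' @export
read_sample_sheet <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    sheet <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    sheet <- utils::read.delim(path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(sheet))
    stop("sample sheet lacks a 'sample_id' column")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  for (nm in c("condition", "fraction", "mouse_id", "compartment"))
    if (nm %in% names(sheet)) sheet[[nm]] <- as.character(sheet[[nm]])
  for (nm in c("timepoint_days", "replicate", "compliance"))
    if (nm %in% names(sheet)) sheet[[nm]] <- as.numeric(sheet[[nm]])
  if ("fraction" %in% names(sheet)) check_fraction(sheet$fraction)
  sheet
}

#' Write an intensity table in the proteinGroups dialect
#'
#' Inverse of [read_protein_groups()]: writes a tab-separated wide table with
#' one `Intensity <sample_id>` column per sample (`NA` written as 0) and a
#' companion sample sheet.
#'
#' @param table an [intensity_table()].
#' @param path output path for the protein table.
#' @param sample_sheet_path output path for the sample sheet (TSV); `NULL` to
#'   skip.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path, sample_sheet_path = NULL) {
  stopifnot(inherits(table, "IntensityTable"))
  vals <- table$values
  vals[is.na(vals)] <- 0
  out <- data.frame(
    `Majority protein IDs` = table$proteins$protein_id,
    `Gene names` = table$proteins$gene_name,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$proteins$sequence) && !all(is.na(table$proteins$sequence)))
    out$Sequence <- table$proteins$sequence
  if (!is.null(table$proteins$n_theoretical_peptides))
    out$`Number of theoretical peptides` <- table$proteins$n_theoretical_peptides
  ints <- as.data.frame(vals, check.names = FALSE)
  names(ints) <- paste0("Intensity ", table$samples$sample_id)
  out <- cbind(out, ints)
  out$Reverse <- ""
  out$`Potential contaminant` <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path)) {
    sheet <- table$samples
    sheet$column <- paste0("Intensity ", sheet$sample_id)
    utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one term per line, tab-separated
#'   `term<TAB>description<TAB>member...`.
#' @param category category label stored on every term, default `"gmt"`.
#' @return An `AnnotationCollection`: named list of terms, each a list with
#'   `label`, `category` and `members` (character vector of gene ids).
#' @export
read_gmt <- function(path, category = "gmt") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (needs term, description, >=1 member): ", l)
    list(label = f[2], category = category, members = unique(f[-(1:2)]))
  })
  names(terms) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(terms))) stop("duplicate term ids in ", path)
  annotation_collection(terms)
}

#' Construct an annotation collection
#'
#' @param terms named list; each element a list with `label`, `category`,
#'   `members`.
#' @return An `AnnotationCollection`.
#' @export
annotation_collection <- function(terms) {
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("terms must be named by term_id")
  for (id in names(terms)) {
    t <- terms[[id]]
    if (length(t$members) < 1) stop("term '", id, "' has no members")
    terms[[id]]$members <- unique(as.character(t$members))
  }
  structure(terms, class = "AnnotationCollection")
}

#' @export
print.AnnotationCollection <- function(x, ...) {
  cat(sprintf("AnnotationCollection: %d terms (%s)\n", length(x),
              paste(unique(vapply(x, `[[`, "", "category")), collapse = ", ")))
  invisible(x)
}

#' Write gene sets to a GMT file
#'
#' @param annotations an `AnnotationCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations), function(id) {
    t <- annotations[[id]]
    paste(c(id, t$label, t$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table with a reproducibility header
#'
#' Writes a TSV preceded by `#`-prefixed comment lines carrying the package
#' version, seed and input checksums, so every emitted table is traceable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list of metadata to record in the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("qdspr ",
                               as.character(utils::packageVersion("qdspr")))),
            meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = ","),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
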