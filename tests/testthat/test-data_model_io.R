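test_that("reverse/contaminant rows are dropped and zeros become missing", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Majority protein IDs\tGene names\tReverse\tPotential contaminant\tIntensity A\tIntensity B",
    "P1\tG1\t\t\t100\t0",
    "REV__P2\tG2\t+\t\t50\t60",
    "P3\tG3\t\t\t0\t300"), tmp)
  writeLines(c("sample_id\tcolumn\tcondition\tfraction\treplicate",
               "A\tIntensity A\tPBS\tTOTAL\t1",
               "B\tIntensity B\tBLEO\tTOTAL\t1"), sheet)
  tab <- read_protein_groups(tmp, sheet)
  expect_equal(nrow(tab$values), 2L)
  expect_equal(tab$proteins$protein_id, c("P1", "P3"))
  expect_equal(unname(attr(tab, "filter_counts")["reverse"]), 1L)
  expect_true(is.na(tab$values["P1", "B"]))
  expect_true(is.na(tab$values["P3", "A"]))
  expect_equal(tab$values["P3", "B"], 300)
})

test_that("read errors name the offending column / protein / fraction", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Majority protein IDs\tIntensity A", "P1\t10", "P1\t20"), tmp)
  writeLines(c("sample_id\tcolumn\tcondition",
               "A\tIntensity A\tPBS"), sheet)
  expect_error(read_protein_groups(tmp, sheet), "duplicate protein_id")
  writeLines(c("Majority protein IDs\tIntensity A", "P1\t10"), tmp)
  writeLines(c("sample_id\tcolumn\tcondition",
               "A\tIntensity ZZ\tPBS"), sheet)
  expect_error(read_protein_groups(tmp, sheet), "Intensity ZZ")
  writeLines(c("sample_id\tcolumn\tcondition\tfraction",
               "A\tIntensity A\tPBS\tNOPE"), sheet)
  expect_error(read_protein_groups(tmp, sheet), "unknown fraction")
})

test_that("write -> read round-trip preserves all non-missing cells", {
  set.seed(3)
  vals <- matrix(round(2^rnorm(40, 24, 2), 3), 5, 8)
  vals[sample(40, 6)] <- NA
  tab <- make_table(vals, condition = rep(c("PBS", "BLEO"), each = 4))
  pg <- withr::local_tempfile(fileext = ".txt")
  sh <- withr::local_tempfile(fileext = ".tsv")
  write_protein_groups(tab, pg, sh)
  back <- read_protein_groups(pg, sh)
  expect_equal(back$values, tab$values)
  expect_equal(back$samples$condition, tab$samples$condition)
  # idempotence: a second round trip is cell-exact too
  pg2 <- withr::local_tempfile(fileext = ".txt")
  sh2 <- withr::local_tempfile(fileext = ".tsv")
  write_protein_groups(back, pg2, sh2)
  expect_equal(read_protein_groups(pg2, sh2)$values, tab$values)
})

test_that("tryptic peptide counting follows the KP-suppressed cleavage rule", {
  expect_equal(count_tryptic_peptides("AAAAAAAK"), 1L)
  # peptides AAAAAAAK, R (below min_len), CCCCCCC
  expect_equal(count_tryptic_peptides("AAAAAAAKRCCCCCCC"), 2L)
  # KP suppression: a single 15-mer
  expect_equal(count_tryptic_peptides("AAAAAAAKPGGGGGG"), 1L)
  expect_warning(expect_equal(count_tryptic_peptides(""), 0L), "empty")
  expect_error(count_tryptic_peptides("AAAB1AAA"), "illegal")
})

test_that("tryptic counting agrees with a residue-walking oracle", {
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:300) {
    s <- paste(sample(aa, sample(5:500, 1), replace = TRUE), collapse = "")
    expect_equal(count_tryptic_peptides(s), oracle_tryptic(s), info = s)
  }
})

test_that("iBAQ and stoichiometry behave as documented", {
  expect_equal(compute_ibaq(1e9, 10), 1e8)
  expect_warning(res <- compute_ibaq(c(10, 20), c(5, 0)), "0 theoretical")
  expect_true(is.na(res[2]))
  st <- ibaq_stoichiometry(c(A = 3, B = 1))
  expect_equal(st, c(A = 0.75, B = 0.25))
  st2 <- ibaq_stoichiometry(c(A = 3, B = NA, C = 1))
  expect_equal(sum(st2, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(unname(st2["A"]), 0.75)
})

test_that("omics matching filters on log2 FPKM and reports Pearson r", {
  pr <- c(g1 = 1, g2 = -1, g3 = 0.5)
  rr <- c(g1 = 1, g2 = -1, g3 = 0.5)
  fpkm <- c(g1 = 4, g2 = 2, g3 = 0.25)  # g3 log2 = -2 < -1
  m <- match_omics(pr, rr, fpkm)
  expect_equal(m$gene, c("g1", "g2"))
  expect_equal(attr(m, "pearson_r"), 1.0)
  set.seed(5)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.3)
  nm <- sprintf("g%02d", 1:50)
  names(x) <- names(y) <- nm
  fp <- setNames(rep(10, 50), nm)
  m2 <- match_omics(x, y, fp)
  expect_equal(attr(m2, "pearson_r"), oracle_pearson(x, y), tolerance = 1e-12)
  expect_error(match_omics(c(a = 1), c(b = 1), c(b = 2)), "no genes")
})

test_that("row z-scoring yields mean 0 / sd 1 and preserves missingness", {
  m <- rbind(c(1, 2, 3), c(5, 5, 5), c(1, NA, 3))
  expect_warning(z <- zscore_rows(m), "zero spread")
  expect_equal(z[1, ], c(-1, 0, 1))
  expect_true(all(is.na(z[2, ])))
  expect_true(is.na(z[3, 2]))
  set.seed(2)
  r <- matrix(rnorm(200), 10)
  zr <- zscore_rows(r)
  expect_equal(rowMeans(zr), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(zr, 1, sd), rep(1, 10), tolerance = 1e-12)
})

test_that("GMT files round-trip and malformed lines error", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  ann <- annotation_collection(list(
    ECM = list(label = "core matrisome", category = "class",
               members = c("Col1a1", "Fn1", "Tnc")),
    CYTO = list(label = "cytosol", category = "class",
                members = c("Gapdh", "Actb"))))
  write_gmt(ann, tmp)
  back <- read_gmt(tmp)
  expect_equal(names(back), c("ECM", "CYTO"))
  expect_equal(back$ECM$members, ann$ECM$members)
  writeLines("justaterm\tdesc", tmp)
  expect_error(read_gmt(tmp), "malformed")
  expect_error(annotation_collection(list(X = list(label = "x", category = "c",
                                                   members = character(0)))),
               "no members")
})
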