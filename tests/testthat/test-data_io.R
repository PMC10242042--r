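fixture <- function(name) {
  system.file("extdata", name, package = "txpod", mustWork = TRUE)
}

write_tmp <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

make_count_files <- function(n_probes = 20, n_conc = 10, n_rep = 3,
                             sep = "\t") {
  conc <- c(0, 10^seq(-3, 2, length.out = n_conc))
  design <- data.frame(
    sample_id = sprintf("s%02d_r%d", rep(seq_along(conc), each = n_rep),
                        rep(seq_len(n_rep), length(conc))),
    concentration_uM = rep(conc, each = n_rep),
    replicate = rep(seq_len(n_rep), length(conc)))
  counts <- matrix(rpois(n_probes * nrow(design), 100), n_probes,
                   dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                                   design$sample_id))
  counts_df <- data.frame(probe_id = rownames(counts), counts,
                          check.names = FALSE)
  list(counts = write_tmp(counts_df, sep = sep),
       design = write_tmp(design, sep = sep),
       design_df = design, counts_mat = counts)
}

test_that("well-formed counts and design round-trip into an experiment", {
  set.seed(11)
  f <- make_count_files()
  ex <- read_counts_and_design(f$counts, f$design,
                               inventory_row = data.frame(
                                 casrn = "50-00-0", model = "MCF-7",
                                 exposure_days = 2))
  expect_s3_class(ex, "txpod_experiment")
  expect_length(ex$concentrations, 11)
  expect_identical(dim(ex$counts), c(20L, 33L))
  expect_equal(ex$chemical_id, "50-00-0")
  # design index sorted ascending by concentration
  expect_true(!is.unsorted(ex$design$concentration_uM))
  # comma-separated input parses identically (delimiter auto-detection)
  f2 <- make_count_files(sep = ",")
  ex2 <- read_counts_and_design(f2$counts, f2$design)
  expect_length(ex2$concentrations, 11)
})

test_that("too few nonzero concentrations is a design error naming the chemical", {
  set.seed(12)
  f <- make_count_files(n_conc = 4)
  expect_error(
    read_counts_and_design(f$counts, f$design,
                           inventory_row = data.frame(
                             casrn = "64-17-5", model = "x", exposure_days = 1)),
    class = "txpod_design_error")
  err <- tryCatch(
    read_counts_and_design(f$counts, f$design,
                           inventory_row = data.frame(
                             casrn = "64-17-5", model = "x", exposure_days = 1)),
    error = identity)
  expect_match(conditionMessage(err), "64-17-5")
})

test_that("negative or fractional counts are data errors identifying the cell", {
  set.seed(13)
  f <- make_count_files(n_probes = 5)
  raw <- read.delim(f$counts, check.names = FALSE)
  raw[3, 4] <- -2
  bad <- write_tmp(raw)
  err <- tryCatch(read_counts_and_design(bad, f$design), error = identity)
  expect_s3_class(err, "txpod_data_error")
  expect_match(conditionMessage(err), "p003")
  # sample id mismatch is a schema error
  d2 <- read.delim(f$design)
  d2$sample_id[1] <- "nonexistent"
  expect_error(read_counts_and_design(f$counts, write_tmp(d2)),
               class = "txpod_schema_error")
})

test_that("GMT parsing dedups members and validates line shape", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("GO:1\tdesc\tg1\tg2\tg3",
               "GO:2\tdesc\tg1\tg1\tg2"), gmt)
  gs <- read_gene_sets(gmt, "GO-BP")
  expect_equal(unname(gs$sizes[c("GO:1", "GO:2")]), c(3L, 2L))
  expect_setequal(gs$sets[["GO:2"]], c("g1", "g2"))

  writeLines(c("GO:1\tdesc\tg1", "GO:2\tonlytwo"), gmt)
  err <- tryCatch(read_gene_sets(gmt), error = identity)
  expect_s3_class(err, "txpod_schema_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(character(0), gmt)
  empty <- read_gene_sets(gmt)
  expect_length(empty$sets, 0)
})

test_that("reference tables parse, join by CASRN, and flag unmodelable chemicals", {
  tk <- write_tmp(data.frame(casrn = c("50-00-0", "64-17-5"),
                             mw = c(30, 46), fub = c(0.5, 0.9),
                             clint = c(10, 0)))
  # the Table 2 fixture preserves its printed CASRN quirks verbatim, so the
  # reader must warn but keep those rows
  expect_warning(
    tabs <- read_reference_tables(fixture("chemical_inventory.tsv"),
                                  fixture("apical_pods.tsv"), tk),
    "malformed CASRN")
  expect_equal(nrow(tabs$apical), 40)
  i <- which.min(tabs$apical$effect_level)
  expect_equal(tabs$apical$effect_level[i], 0.000078)
  expect_equal(tabs$apical$casrn[i], "1162-65-8")
  # fabs defaults to 1 when the column is absent
  expect_equal(tabs$tk$fabs, c(1, 1))
  # a chemical with an apical POD but no TK row is present but unmodelable
  cov <- tabs$coverage
  afb1 <- cov[cov$casrn == "1162-65-8", ]
  expect_true(afb1$has_apical)
  expect_false(afb1$modelable)
  # non-positive effect level rejected
  bad <- write_tmp(data.frame(casrn = "50-00-0", study_type = "Repeat Dose",
                              method = "NOAEL", effect_level = 0))
  expect_error(read_reference_tables(pod_path = bad),
               class = "txpod_data_error")
})

test_that("inventory counts and experiment expansion match the study accounting", {
  tabs <- read_reference_tables(fixture("chemical_inventory.tsv"))
  expect_equal(length(unique(tabs$inventory$casrn)), 117)
  expanded <- expand_experiments(tabs$inventory)
  expect_equal(nrow(expanded), 179)
  # each expanded row is scalar-valued
  expect_false(any(grepl(";", expanded$model)))
  expect_type(expanded$exposure_days, "double")
})

test_that("simulated experiments round-trip through the exchange formats", {
  sim <- simulate_experiment(sim_config(n_probes = 30), seed = 4, "1234-56-7")
  dir <- tempfile()
  write_simulated_experiment(sim, dir)
  ex <- read_counts_and_design(file.path(dir, "counts.tsv"),
                               file.path(dir, "design.tsv"))
  expect_equal(unname(ex$counts), unname(sim$experiment$counts))
  expect_equal(ex$design$concentration_uM,
               sim$experiment$design$concentration_uM)
})
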