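# Readers and validators for all tabular inputs: counts + design, GMT gene
# sets, the chemical inventory, apical (in vivo) PODs and toxicokinetic
# parameters. Everything downstream consumes the structures built here.

#' Construct and validate a concentration-response experiment
#'
#' An experiment is the unit of analysis: one chemical in one cell model at
#' one exposure duration, with a probe-by-sample integer count matrix and a
#' per-sample design giving the exposure concentration (µM; 0 encodes the
#' solvent control) and replicate index.
#'
#' @param counts integer matrix, probes in rows, samples in columns. Column
#'   names must match `design$sample_id` exactly (order is taken from the
#'   design, sorted by concentration).
#' @param design data.frame with columns `sample_id`, `concentration_uM`
#'   (>= 0) and `replicate`.
#' @param chemical_id CASRN string identifying the chemical.
#' @param cell_model cell model label (e.g. "MCF-7").
#' @param exposure_days positive exposure duration in days.
#' @param min_nonzero_conc minimum number of distinct nonzero concentrations
#'   required (default 5); a zero-concentration control group is always
#'   required.
#'
#' @return An object of class `txpod_experiment`: a list with elements
#'   `counts`, `design` (sorted by concentration then replicate),
#'   `chemical_id`, `cell_model`, `exposure_days`, `concentrations`
#'   (sorted distinct values including 0).
#' @export
new_experiment <- function(counts, design, chemical_id, cell_model = "cell",
                           exposure_days = 1, min_nonzero_conc = 5L) {
  require_columns(design, c("sample_id", "concentration_uM", "replicate"),
                  "design table")
  design$sample_id <- as.character(design$sample_id)
  design$concentration_uM <- as.numeric(design$concentration_uM)
  if (anyDuplicated(design$sample_id)) {
    schema_error("design sample ids are not unique")
  }
  if (any(is.na(design$concentration_uM)) || any(design$concentration_uM < 0)) {
    design_error(sprintf("chemical %s: concentrations must be >= 0", chemical_id))
  }
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) schema_error("count matrix has no sample names")
  extra <- setdiff(colnames(counts), design$sample_id)
  absent <- setdiff(design$sample_id, colnames(counts))
  if (length(extra) || length(absent)) {
    schema_error(sprintf(
      "sample ids differ between counts and design (counts-only: %s; design-only: %s)",
      paste(extra, collapse = ",") , paste(absent, collapse = ",")))
  }
  bad <- which(counts < 0 | counts != round(counts) | is.na(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    data_error(sprintf(
      "counts must be non-negative integers; first offender: probe '%s', sample '%s'",
      rownames(counts)[bad[1, 1]] %||% bad[1, 1], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "double"
  conc <- sort(unique(design$concentration_uM))
  if (!0 %in% conc) {
    design_error(sprintf("chemical %s: no solvent control (concentration 0)",
                         chemical_id))
  }
  if (sum(conc > 0) < min_nonzero_conc) {
    design_error(sprintf(
      "chemical %s: %d nonzero concentrations found, a minimum of %d is required",
      chemical_id, sum(conc > 0), min_nonzero_conc))
  }
  ord <- order(design$concentration_uM, design$replicate)
  design <- design[ord, , drop = FALSE]
  rownames(design) <- NULL
  counts <- counts[, design$sample_id, drop = FALSE]
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("probe_%05d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, design = design,
                 chemical_id = as.character(chemical_id),
                 cell_model = cell_model,
                 exposure_days = exposure_days,
                 concentrations = conc),
            class = "txpod_experiment")
}

#' @export
print.txpod_experiment <- function(x, ...) {
  cat(sprintf(
    "<txpod_experiment> %s | %s | %g d | %d probes x %d samples | %d conc groups\n",
    x$chemical_id, x$cell_model, x$exposure_days,
    nrow(x$counts), ncol(x$counts), length(x$concentrations)))
  invisible(x)
}

#' Read a count matrix and design table into an experiment
#'
#' The count file has the probe id in the first column and one column per
#' sample; the design file has columns `sample_id`, `concentration_uM` and
#' `replicate`. Delimiters (tab/comma) are auto-detected per file.
#'
#' @param counts_path path to the probe-by-sample count table.
#' @param design_path path to the per-sample design table.
#' @param inventory_row optional single-row data.frame (as produced by
#'   [read_reference_tables()]) providing `casrn`, `model`, `exposure_days`;
#'   when omitted the experiment is labelled "unknown".
#' @inheritParams new_experiment
#' @return A validated [new_experiment()] object.
#' @export
read_counts_and_design <- function(counts_path, design_path,
                                   inventory_row = NULL,
                                   min_nonzero_conc = 5L) {
  raw <- read_table_auto(counts_path)
  if (ncol(raw) < 2L) schema_error("count table needs a probe id column plus samples")
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- as.character(raw[[1]])
  design <- read_table_auto(design_path)
  new_experiment(
    counts, design,
    chemical_id = inventory_row$casrn %||% "unknown",
    cell_model = inventory_row$model %||% "unknown",
    exposure_days = inventory_row$exposure_days %||% NA_real_,
    min_nonzero_conc = min_nonzero_conc)
}

#' Read a GMT gene-set collection
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Duplicate members within a set are collapsed; the set size
#' is the deduplicated member count unless `sizes` supplies annotated totals.
#'
#' @param gmt_path path to the GMT file.
#' @param database_label label for the source database (e.g. "GO-BP").
#' @param sizes optional named integer vector of total annotated gene counts
#'   per set id, overriding member counts (used when the GMT carries only the
#'   measured subset of each set).
#' @return A `txpod_genesets` list with `database_label`, `sets` (named list
#'   of character vectors) and `sizes` (named integer vector).
#' @export
read_gene_sets <- function(gmt_path, database_label = "geneset",
                           sizes = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); names_map <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      schema_error(sprintf("GMT line %d has %d field(s); need id, description, >=1 member",
                           i, length(fields)))
    }
    id <- fields[[1]]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    sets[[id]] <- members
    names_map[[id]] <- fields[[2]]
  }
  set_sizes <- vapply(sets, length, integer(1))
  if (!is.null(sizes)) {
    hit <- intersect(names(set_sizes), names(sizes))
    set_sizes[hit] <- as.integer(sizes[hit])
  }
  structure(list(database_label = database_label, sets = sets,
                 set_names = names_map, sizes = set_sizes),
            class = "txpod_genesets")
}

#' Read a probe-to-gene map
#'
#' @param path two-column table (`probe_id`, `gene_id`); extra columns are
#'   ignored.
#' @return named character vector: probe id -> gene id.
#' @export
read_probe_map <- function(path) {
  df <- read_table_auto(path)
  require_columns(df, c("probe_id", "gene_id"), "probe map")
  setNames(as.character(df$gene_id), as.character(df$probe_id))
}

# very light CASRN shape check: digits-digits-digit
casrn_ok <- function(x) grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)

#' Read the chemical inventory, apical POD and toxicokinetic tables
#'
#' The inventory mirrors the study listing (dataset, chemical_name, abbrev,
#' casrn, model, exposure_days; multi-valued model/exposure_days are
#' semicolon-separated). The apical table carries one row per (chemical,
#' study) with a positive effect level in mg/kg-bw/day. The TK table carries
#' molecular weight (g/mol), fraction unbound in plasma, intrinsic hepatic
#' clearance (µL/min/10^6 hepatocytes) and optionally the fraction absorbed
#' by gut (defaults to 1: full absorption). CASRN is the join key across all
#' tables; chemicals with apical data but no TK row are flagged
#' not-modelable rather than dropped.
#'
#' @param inventory_path,pod_path,tk_path file paths; any may be `NULL` to
#'   skip that table.
#' @return list with elements `inventory`, `apical` (class
#'   `txpod_apical_table`), `tk` (class `txpod_tk_table`), and `coverage`, a
#'   per-CASRN data.frame flagging presence in each table (`modelable` =
#'   present in the TK table).
#' @export
read_reference_tables <- function(inventory_path = NULL, pod_path = NULL,
                                  tk_path = NULL) {
  inventory <- apical <- tk <- NULL
  if (!is.null(inventory_path)) {
    inventory <- read_table_auto(inventory_path, colClasses = "character")
    require_columns(inventory, c("casrn", "model", "exposure_days"),
                    "chemical inventory")
    if (any(!casrn_ok(inventory$casrn))) {
      warning(sprintf("inventory: %d malformed CASRN(s) kept as-is",
                      sum(!casrn_ok(inventory$casrn))))
    }
  }
  if (!is.null(pod_path)) {
    apical <- read_table_auto(pod_path)
    require_columns(apical, c("casrn", "study_type", "method", "effect_level"),
                    "apical POD table")
    apical$casrn <- as.character(apical$casrn)
    apical$effect_level <- as.numeric(apical$effect_level)
    if (any(is.na(apical$effect_level) | apical$effect_level <= 0)) {
      data_error("apical POD table: effect levels must be positive")
    }
    if (any(!nzchar(apical$casrn))) data_error("apical POD table: empty CASRN")
    if (any(!casrn_ok(apical$casrn))) {
      warning(sprintf("apical POD table: %d malformed CASRN(s) kept as-is",
                      sum(!casrn_ok(apical$casrn))))
    }
    class(apical) <- c("txpod_apical_table", "data.frame")
  }
  if (!is.null(tk_path)) {
    tk <- read_table_auto(tk_path)
    require_columns(tk, c("casrn", "mw", "fub", "clint"), "TK table")
    tk$casrn <- as.character(tk$casrn)
    for (col in c("mw", "fub", "clint")) tk[[col]] <- as.numeric(tk[[col]])
    if (is.null(tk$fabs)) tk$fabs <- 1 else {
      tk$fabs <- as.numeric(tk$fabs)
      tk$fabs[is.na(tk$fabs)] <- 1  # full gut absorption assumed when absent
    }
    if (any(is.na(tk$mw) | tk$mw <= 0)) data_error("TK table: MW must be > 0")
    if (any(is.na(tk$fub) | tk$fub < 0 | tk$fub > 1)) {
      data_error("TK table: fraction unbound must lie in [0, 1]")
    }
    if (any(is.na(tk$clint) | tk$clint < 0)) {
      data_error("TK table: intrinsic clearance must be >= 0")
    }
    class(tk) <- c("txpod_tk_table", "data.frame")
  }
  all_casrn <- unique(c(inventory$casrn, apical$casrn, tk$casrn))
  coverage <- data.frame(
    casrn = all_casrn,
    in_inventory = all_casrn %in% (inventory$casrn %||% character(0)),
    has_apical = all_casrn %in% (apical$casrn %||% character(0)),
    modelable = all_casrn %in% (tk$casrn %||% character(0)),
    stringsAsFactors = FALSE)
  list(inventory = inventory, apical = apical, tk = tk, coverage = coverage)
}

#' Expand the chemical inventory into its concentration-response experiments
#'
#' Each inventory row contributes one experiment per exposure duration per
#' cell-model state (semicolon-separated multi-values), reproducing the
#' study's accounting of experiments across datasets.
#'
#' @param inventory data.frame as returned in
#'   `read_reference_tables()$inventory`.
#' @return data.frame with one row per experiment: all inventory columns plus
#'   scalar `model` and `exposure_days`.
#' @export
expand_experiments <- function(inventory) {
  require_columns(inventory, c("casrn", "model", "exposure_days"),
                  "chemical inventory")
  rows <- lapply(seq_len(nrow(inventory)), function(i) {
    row <- inventory[i, , drop = FALSE]
    models <- strsplit(row$model, ";", fixed = TRUE)[[1]]
    days <- strsplit(as.character(row$exposure_days), ";", fixed = TRUE)[[1]]
    grid <- expand.grid(model = trimws(models),
                        exposure_days = as.numeric(trimws(days)),
                        stringsAsFactors = FALSE)
    out <- row[rep(1L, nrow(grid)), setdiff(names(row),
                                            c("model", "exposure_days")),
               drop = FALSE]
    cbind(out, grid, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
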