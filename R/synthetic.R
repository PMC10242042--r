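# TempO-Seq-like concentration-response simulator with known ground truth.
# Counts are negative binomial around a baseline mean; responsive probes get
# a Hill-shaped shift on the log2 scale, which yields closed-form true BMCs.

#' Simulation configuration
#'
#' Defaults emulate the source designs: 10 approximately half-log-spaced
#' concentrations spanning 0.0005-100 µM plus solvent controls, 3 replicates,
#' an S1500+-sized panel (~3,000 probes), and negative-binomial counts whose
#' responsive subset follows mean
#' \eqn{\mu_p \cdot 2^{sE c^h/(AC_{50}^h + c^h)}}.
#'
#' @param n_probes panel size (default 3000, S1500+-like).
#' @param fraction_responsive fraction of probes given a true response
#'   (default 0.1).
#' @param concentrations nonzero exposure concentrations in µM (default 10
#'   log-spaced values over \[0.0005, 100\]); 0 (control) is added
#'   automatically.
#' @param n_replicates replicates per concentration group, controls included
#'   (default 3).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-probe
#'   baseline mean counts (defaults log(100), 1.2 — a skewed panel with a
#'   median around 100 counts).
#' @param dispersion negative-binomial dispersion phi (var = mu + phi mu^2;
#'   default 0.05, a low-dispersion targeted assay).
#' @param libsize_sdlog lognormal sd of per-sample library-size factors
#'   (median 1; default 0.15).
#' @param ac50_range AC50 drawn log-uniformly from this range, µM (default
#'   c(0.005, 50), inside the tested range).
#' @param e_range max |log2 shift| E drawn uniformly from this range
#'   (default c(1, 3)).
#' @param h_range Hill coefficient drawn uniformly (default c(1, 3)).
#' @param p_increase probability a responsive probe goes up (default 0.5).
#' @param delta_log2 benchmark shift used for ground-truth BMCs; `NULL`
#'   (default) uses each probe's approximate within-group SD on the log2
#'   scale, matching a BMR of one standard deviation.
#' @return list of class `txpod_sim_config`.
#' @export
sim_config <- function(n_probes = 3000L,
                       fraction_responsive = 0.1,
                       concentrations = 10^seq(log10(5e-4), log10(100),
                                               length.out = 10),
                       n_replicates = 3L,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1.2,
                       dispersion = 0.05,
                       libsize_sdlog = 0.15,
                       ac50_range = c(0.005, 50),
                       e_range = c(1, 3),
                       h_range = c(1, 3),
                       p_increase = 0.5,
                       delta_log2 = NULL) {
  cfg <- list(n_probes = as.integer(n_probes),
              fraction_responsive = fraction_responsive,
              concentrations = sort(concentrations),
              n_replicates = as.integer(n_replicates),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              dispersion = dispersion,
              libsize_sdlog = libsize_sdlog,
              ac50_range = ac50_range, e_range = e_range, h_range = h_range,
              p_increase = p_increase, delta_log2 = delta_log2)
  nums <- unlist(cfg[!vapply(cfg, is.null, logical(1))])
  if (any(!is.finite(nums))) config_error("all simulation parameters must be finite")
  if (fraction_responsive < 0 || fraction_responsive > 1) {
    config_error("fraction_responsive must lie in [0, 1]")
  }
  if (any(cfg$concentrations <= 0)) {
    config_error("nonzero concentrations must be positive; 0 is added automatically")
  }
  if (min(e_range) <= 0) config_error("E must be > 0 for responsive probes")
  class(cfg) <- "txpod_sim_config"
  cfg
}

# Hill shift on the log2 scale
hill_shift <- function(c, e, ac50, h) e * c^h / (ac50^h + c^h)

#' Closed-form ground-truth BMC for a simulated probe
#'
#' Solves \eqn{E c^h / (AC_{50}^h + c^h) = \delta} for c:
#' \eqn{c = AC_{50} (\delta/(E-\delta))^{1/h}}.
#'
#' @param probe_truth list or single-row data.frame with `e`, `ac50`, `h`
#'   (and optionally `responsive`).
#' @param delta_log2 benchmark shift on the log2 scale; must satisfy
#'   0 < delta_log2 < E.
#' @return concentration in µM.
#' @export
true_bmc <- function(probe_truth, delta_log2) {
  if (!is.null(probe_truth$responsive) && !isTRUE(as.logical(probe_truth$responsive))) {
    config_error("true_bmc is defined only for responsive probes")
  }
  e <- probe_truth$e; ac50 <- probe_truth$ac50; h <- probe_truth$h
  if (delta_log2 <= 0) config_error("delta_log2 must be positive")
  if (delta_log2 >= e) {
    config_error(sprintf(
      "delta_log2 (%g) >= E (%g): the Hill curve never reaches the benchmark shift",
      delta_log2, e))
  }
  ac50 * (delta_log2 / (e - delta_log2))^(1 / h)
}

#' Simulate a concentration-response experiment with known truth
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @param chemical_id CASRN-style label for the simulated chemical; the
#'   random stream is derived from `(seed, chemical_id)` so per-chemical
#'   simulation is reproducible under any execution order.
#' @return list with `experiment` (a [new_experiment()]), `probe_map`
#'   (probe -> gene, one probe per gene), and `truth`, a data.frame with
#'   per-probe `responsive`, `sign`, `ac50`, `e`, `h`, `delta_log2`,
#'   `true_bmc` (NA for null probes or when the curve cannot reach the
#'   shift) and `bmc_below_range`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1L,
                                chemical_id = "sim-chem-1") {
  stopifnot(inherits(config, "txpod_sim_config"))
  n_resp <- round(config$fraction_responsive * config$n_probes)
  if (config$fraction_responsive > 0 && n_resp < 1) {
    config_error("fraction_responsive * n_probes < 1: no responsive probe can be drawn")
  }
  set.seed(child_seed(seed, chemical_id))
  p <- config$n_probes
  conc_groups <- c(0, config$concentrations)
  design <- data.frame(
    sample_id = sprintf("s%02d_r%d", rep(seq_along(conc_groups),
                                         each = config$n_replicates),
                        rep(seq_len(config$n_replicates),
                            length(conc_groups))),
    concentration_uM = rep(conc_groups, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(conc_groups)),
    stringsAsFactors = FALSE)
  n_s <- nrow(design)

  base_mu <- rlnorm(p, config$baseline_meanlog, config$baseline_sdlog)
  lib <- rlnorm(n_s, 0, config$libsize_sdlog)
  responsive <- rep(FALSE, p)
  responsive[sample.int(p, n_resp)] <- TRUE
  sgn <- ifelse(runif(p) < config$p_increase, 1, -1)
  ac50 <- exp(runif(p, log(config$ac50_range[1]), log(config$ac50_range[2])))
  e <- runif(p, config$e_range[1], config$e_range[2])
  h <- runif(p, config$h_range[1], config$h_range[2])
  sgn[!responsive] <- NA; ac50[!responsive] <- NA
  e[!responsive] <- NA; h[!responsive] <- NA

  shift <- matrix(0, p, n_s)
  if (n_resp > 0) {
    idx <- which(responsive)
    for (j in seq_len(n_s)) {
      cj <- design$concentration_uM[j]
      shift[idx, j] <- sgn[idx] * hill_shift(cj, e[idx], ac50[idx], h[idx])
    }
  }
  mu <- (base_mu %o% lib) * 2^shift
  counts <- matrix(rnbinom(p * n_s, size = 1 / config$dispersion, mu = mu),
                   p, n_s,
                   dimnames = list(sprintf("probe_%05d", seq_len(p)),
                                   design$sample_id))

  # per-probe benchmark shift: approximate within-group SD of log2 counts
  # (lognormal approximation to the NB coefficient of variation)
  delta <- config$delta_log2 %||%
    (sqrt(log(1 + 1 / base_mu + config$dispersion)) / log(2))
  delta <- rep(delta, length.out = p)
  tb <- rep(NA_real_, p)
  ok <- responsive & delta < e
  tb[ok] <- ac50[ok] * (delta[ok] / (e[ok] - delta[ok]))^(1 / h[ok])
  truth <- data.frame(
    probe_id = rownames(counts), responsive = responsive, sign = sgn,
    ac50 = ac50, e = e, h = h, delta_log2 = delta, true_bmc = tb,
    bmc_below_range = !is.na(tb) & tb < min(config$concentrations),
    stringsAsFactors = FALSE)

  experiment <- new_experiment(counts, design, chemical_id = chemical_id,
                               cell_model = "simulated",
                               exposure_days = 1)
  probe_map <- setNames(sprintf("gene_%05d", seq_len(p)), rownames(counts))
  list(experiment = experiment, probe_map = probe_map, truth = truth)
}

#' Simulate matching toxicokinetic and apical-POD reference tables
#'
#' Toxicokinetic parameters are drawn from realistic screening-level ranges
#' (MW 100-500 g/mol, fraction unbound log-uniform 0.05-1, intrinsic
#' clearance log-uniform 0.5-50 µL/min/10^6 cells). Each chemical's apical
#' POD is constructed as its designed administered equivalent dose times
#' `10^margin`, so the expected sign of the final log10-ratio is known by
#' construction: margin +1 designs a positive ratio, margin -1 designs an
#' outlier.
#'
#' @param chemicals data.frame with columns `casrn` and `designed_tpod_uM`.
#' @param seed integer seed.
#' @param margin designed log10 margin between the apical POD and the
#'   designed AED; scalar or one per chemical.
#' @param physiology,n_draws,cv passed to [css_quantile_mc()] when
#'   constructing the designed AED.
#' @return list with `tk` (class `txpod_tk_table`), `apical` (class
#'   `txpod_apical_table`) and `designed`, a per-chemical data.frame holding
#'   the designed AED, margin and expected outlier flag.
#' @export
simulate_reference <- function(chemicals, seed = 1L, margin = 1,
                               physiology = physiology_defaults(),
                               n_draws = 1000L, cv = 0.3) {
  stopifnot(is.data.frame(chemicals), all(c("casrn", "designed_tpod_uM") %in%
                                            names(chemicals)))
  n <- nrow(chemicals)
  margin <- rep(margin, length.out = n)
  set.seed(child_seed(seed, "reference-tables"))
  tk <- data.frame(
    casrn = chemicals$casrn,
    mw = runif(n, 100, 500),
    fub = exp(runif(n, log(0.05), log(1))),
    clint = exp(runif(n, log(0.5), log(50))),
    fabs = 1,
    stringsAsFactors = FALSE)
  class(tk) <- c("txpod_tk_table", "data.frame")

  css95 <- vapply(seq_len(n), function(i) {
    css_quantile_mc(tk[i, ], physiology = physiology, n_draws = n_draws,
                    cv = cv, seed = child_seed(seed, paste0("css-", tk$casrn[i])))$css_q95
  }, numeric(1))
  designed_aed <- chemicals$designed_tpod_uM / css95
  apical <- data.frame(
    casrn = chemicals$casrn,
    study_type = "Repeat Dose",
    method = "NOAEL",
    effect_level = designed_aed * 10^margin,
    stringsAsFactors = FALSE)
  class(apical) <- c("txpod_apical_table", "data.frame")
  designed <- data.frame(
    casrn = chemicals$casrn, designed_tpod_uM = chemicals$designed_tpod_uM,
    css_q95 = css95, designed_aed = designed_aed, margin = margin,
    expect_outlier = margin < 0, stringsAsFactors = FALSE)
  list(tk = tk, apical = apical, designed = designed)
}

#' Simulate a gene-set collection over a gene universe
#'
#' Draws `n_sets` sets of size `set_size` uniformly from `gene_ids`,
#' mimicking a pathway database restricted to the measured panel.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_sets number of sets (default 50).
#' @param set_size members per set (default 20; recycled).
#' @param seed integer seed.
#' @param database_label label for the collection.
#' @return a `txpod_genesets` object compatible with
#'   [tpod_lowest_gene_set()].
#' @export
simulate_gene_sets <- function(gene_ids, n_sets = 50L, set_size = 20L,
                               seed = 1L, database_label = "SIM") {
  set.seed(child_seed(seed, paste0("genesets-", database_label)))
  set_size <- rep(set_size, length.out = n_sets)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(gene_ids, min(set_size[i], length(gene_ids)))
  })
  names(sets) <- sprintf("%s:%04d", database_label, seq_len(n_sets))
  structure(list(database_label = database_label, sets = sets,
                 set_names = setNames(names(sets), names(sets)),
                 sizes = vapply(sets, length, integer(1))),
            class = "txpod_genesets")
}

#' Write a simulated experiment to disk in the package's exchange formats
#'
#' Emits the same TSV formats [read_counts_and_design()] reads, plus a JSON
#' manifest recording the configuration and seed.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param config,seed the configuration and seed used (stored in the
#'   manifest when jsonlite is available).
#' @return invisibly, the paths written.
#' @export
write_simulated_experiment <- function(sim, dir, config = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  design_path <- file.path(dir, "design.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  counts <- data.frame(probe_id = rownames(sim$experiment$counts),
                       sim$experiment$counts, check.names = FALSE)
  write.table(counts, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$experiment$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(counts = counts_path, design = design_path, truth = truth_path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(list(seed = seed, config = unclass(config)),
                         manifest, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- c(paths, manifest = manifest)
  }
  invisible(paths)
}
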