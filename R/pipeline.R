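# End-to-end drivers: one experiment -> gene-level BMCs -> tPODs, and a
# cohort of experiments -> AED records -> comparison against apical PODs.

#' Run the tPOD workflow on one experiment
#'
#' Normalizes to log2 CPM, prefilters probes (Williams trend p < 0.05 and
#' max fold change >= 1.5), fits the model family and derives BMCs with
#' profile bounds, applies the post-filters, collapses to genes, and
#' derives the five tPODs.
#'
#' @param experiment a [new_experiment()].
#' @param probe_map named character vector, probe -> gene.
#' @param collections gene-set collection(s) or NULL.
#' @param seed integer seed for the permutation stream.
#' @param config optional list of overrides: `p_threshold`, `fc_threshold`,
#'   `B`, `bmr_k`, `conf`, `alpha_nested`, plus the [derive_all()] keys.
#' @return list with `prefilter` (per-probe trend table), `records`
#'   (retained probe-level BMC records; dropped rows in
#'   `attr(,"dropped")`), `gene_bmcs` (gene-level table), `tpods`
#'   (a [derive_all()] result) and `exprs`.
#' @export
run_experiment <- function(experiment, probe_map, collections = NULL,
                           seed = 1L, config = list()) {
  cfg <- function(key, default) config[[key]] %||% default
  exprs <- normalize_log2cpm(experiment)
  pf <- prefilter_probes(exprs,
                         p_threshold = cfg("p_threshold", 0.05),
                         fc_threshold = cfg("fc_threshold", 1.5),
                         B = cfg("B", 999L),
                         seed = child_seed(seed, paste0("prefilter-",
                                                        experiment$chemical_id)))
  conc <- experiment$concentrations
  c_top <- max(conc)
  records <- fit_bmc(exprs, pf$pass,
                     bmr_k = cfg("bmr_k", 1),
                     conf = cfg("conf", 0.95),
                     alpha_nested = cfg("alpha_nested", 0.05))
  retained <- postfilter_records(records, c_top)
  genes <- collapse_to_genes(retained, probe_map)
  gene_bmcs <- setNames(genes$bmc, genes$gene_id)
  tpods <- derive_all(gene_bmcs, collections, config)
  list(prefilter = pf$table, records = retained, gene_bmcs = genes,
       tpods = tpods, exprs = exprs)
}

#' Run a simulated cohort end to end and compare against its designed truth
#'
#' Simulates `n_chemicals` experiments plus matching toxicokinetic and
#' apical tables (apical PODs constructed at a designed log10 `margin` from
#' each chemical's designed AED), runs the full workflow per chemical,
#' converts tPODs to AEDs with the 95th-quantile Css, selects the lowest
#' AED per track, and computes log10 ratios and outlier flags.
#'
#' @param n_chemicals cohort size.
#' @param seed integer master seed.
#' @param margin designed log10 margin (scalar or per-chemical).
#' @param sim_cfg a [sim_config()] for the per-chemical experiments.
#' @param config workflow overrides (see [run_experiment()]).
#' @param n_draws,cv Monte Carlo settings for the Css quantile.
#' @return list with `comparisons` (per track), `aed_records`, `designed`
#'   (the designed truth table), `tpod_tables`, `concordance`.
#' @export
run_cohort <- function(n_chemicals = 8L, seed = 1L, margin = 1,
                       sim_cfg = sim_config(), config = list(),
                       n_draws = 1000L, cv = 0.3) {
  casrns <- sprintf("%d-%02d-%d", 1000 + seq_len(n_chemicals),
                    10 + seq_len(n_chemicals) %% 80, seq_len(n_chemicals) %% 10)
  sims <- list(); designed_tpod <- numeric(n_chemicals)
  for (i in seq_len(n_chemicals)) {
    sims[[i]] <- simulate_experiment(sim_cfg, seed, casrns[i])
    tb <- sims[[i]]$truth$true_bmc
    designed_tpod[i] <- min(tb, na.rm = TRUE)
  }
  ref <- simulate_reference(
    data.frame(casrn = casrns, designed_tpod_uM = designed_tpod,
               stringsAsFactors = FALSE),
    seed = seed, margin = margin, n_draws = n_draws, cv = cv)

  aed_rows <- list(); tpod_tables <- list(); spreads <- numeric(0)
  for (i in seq_len(n_chemicals)) {
    colls <- simulate_gene_sets(unname(sims[[i]]$probe_map),
                                seed = child_seed(seed, casrns[i]))
    res <- run_experiment(sims[[i]]$experiment, sims[[i]]$probe_map,
                          collections = colls, seed = seed, config = config)
    tpod_tables[[casrns[i]]] <- tpod_table(res$tpods, casrns[i], "simulated", 1)
    spreads[casrns[i]] <- res$tpods$spread
    tk_row <- ref$tk[ref$tk$casrn == casrns[i], , drop = FALSE]
    css <- css_quantile_mc(tk_row, n_draws = n_draws, cv = cv,
                           seed = child_seed(seed, paste0("mc-", casrns[i])))
    for (m in names(res$tpods$results)) {
      r <- res$tpods$results[[m]]
      if (!r$active) next
      aed_rows[[length(aed_rows) + 1L]] <- data.frame(
        casrn = casrns[i], method = m, experiment = "sim-1",
        tpod_uM = r$value, css_q95 = css$css_q95,
        aed = aed_from_tpod(r$value, css$css_q95), stringsAsFactors = FALSE)
    }
  }
  aed_records <- do.call(rbind, aed_rows)
  lowest_bmc <- select_lowest_aed(aed_records, "bmc-distribution")
  comparisons <- compare_to_apical(lowest_bmc, ref$apical)
  lowest_gs <- select_lowest_aed(aed_records, "gene-set")
  conc <- concordance_summary(spreads, tpods = NULL,
                              lowest_bmc = lowest_bmc,
                              lowest_geneset = lowest_gs)
  list(comparisons = comparisons, aed_records = aed_records,
       designed = ref$designed, tpod_tables = do.call(rbind, tpod_tables),
       concordance = conc)
}
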