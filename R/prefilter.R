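# Normalization to log2 CPM and the concentration-response prefilter:
# a permutation Williams trend test (p < 0.05) combined with a max
# fold-change filter (|FC| >= 1.5 in at least one concentration).

#' Normalize counts to log2 counts per million
#'
#' Size factors are computed by the median-of-ratios method over probes with
#' all-positive counts across samples (geometric-mean reference), counts are
#' divided by their sample's size factor, and each normalized count is
#' expressed as \eqn{\log_2(\mathrm{count}/\mathrm{total} \times 10^6 + 1)}
#' within its sample.
#'
#' @param experiment a [new_experiment()] object.
#' @return object of class `txpod_exprs`: list with `log2cpm` (matrix, same
#'   dimensions as the counts), `size_factors`, and the experiment `design`.
#' @export
normalize_log2cpm <- function(experiment) {
  stopifnot(inherits(experiment, "txpod_experiment"))
  counts <- experiment$counts
  totals <- colSums(counts)
  if (any(totals == 0)) {
    data_error(sprintf("sample(s) with zero total count: %s",
                       paste(colnames(counts)[totals == 0], collapse = ", ")))
  }
  all_pos <- rowSums(counts <= 0) == 0L
  if (any(all_pos)) {
    logc <- log(counts[all_pos, , drop = FALSE])
    log_geo <- rowMeans(logc)
    sf <- exp(apply(logc - log_geo, 2L, median))
  } else {
    sf <- rep(1, ncol(counts))  # degenerate panel: no reference probes
  }
  norm <- sweep(counts, 2L, sf, "/")
  cpm <- sweep(norm, 2L, colSums(norm), "/") * 1e6
  structure(list(log2cpm = log2(cpm + 1), size_factors = sf,
                 design = experiment$design,
                 chemical_id = experiment$chemical_id),
            class = "txpod_exprs")
}

# group index (1-based, control first) per sample, in concentration order
group_index <- function(design) {
  conc <- sort(unique(design$concentration_uM))
  match(design$concentration_uM, conc)
}

# deterministic permutation matrix (B x n, sample indices) under a seed
make_perms <- function(n, B, seed) {
  set.seed(seed)
  t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
}

williams_from_counts <- function(ge, t_obs, B) {
  (1 + ge) / (B + 1)
}

#' Permutation Williams trend test for a single probe
#'
#' Group means (ordered by concentration, control first) are amalgamated by
#' weighted pool-adjacent-violators to enforce monotonicity from control;
#' the statistic is the amalgamated top-concentration mean minus the raw
#' control mean over its pooled-variance standard error. A p-value per
#' direction comes from permuting sample-to-group labels; the reported
#' two-directional p doubles the smaller one (Bonferroni over directions).
#'
#' @param probe_values numeric vector of log2 CPM values, one per sample.
#' @param design design data.frame with `concentration_uM` per sample, in
#'   the same order as `probe_values`.
#' @param B number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `t_stat` (better direction), `direction` ("up"/"down"),
#'   `p`, and the per-direction `p_up`, `p_down`.
#' @export
williams_trend_p <- function(probe_values, design, B = 999L, seed = 1L) {
  if (B < 99L) config_error("B must be >= 99")
  gi <- group_index(design)
  if (all(probe_values == probe_values[1])) {
    return(list(t_stat = 0, direction = "up", p = 1, p_up = 1, p_down = 1))
  }
  perms <- make_perms(length(probe_values), B, seed)
  res <- cpp_williams(matrix(probe_values, nrow = 1), gi - 1L, perms)
  s2_zero <- is.infinite(res$t_up[1]) || is.infinite(res$t_down[1])
  if (s2_zero) {
    warning("zero pooled within-group variance with unequal group means; p set to the permutation floor")
  }
  p_up <- (1 + res$ge_up[1]) / (B + 1)
  p_down <- (1 + res$ge_down[1]) / (B + 1)
  up_better <- res$t_up[1] >= res$t_down[1]
  list(t_stat = if (up_better) res$t_up[1] else res$t_down[1],
       direction = if (up_better) "up" else "down",
       p = min(1, 2 * min(p_up, p_down)),
       p_up = p_up, p_down = p_down)
}

#' Prefilter probes by trend test and fold change
#'
#' A probe passes when its two-directional permutation Williams p-value is
#' below `p_threshold` and its maximum absolute fold change across
#' concentrations (computed as \eqn{2^{|\bar y_c - \bar y_0|}} on group
#' means of log2 CPM) is at least `fc_threshold` (inclusive).
#'
#' @param exprs a [normalize_log2cpm()] result.
#' @param p_threshold trend p-value gate (default 0.05, strict `<`).
#' @param fc_threshold fold-change gate (default 1.5, inclusive `>=`).
#' @param B,seed permutation count and seed (shared permutation stream
#'   across probes).
#' @return list with `pass` (character vector of passing probe ids) and
#'   `table`, a per-probe data.frame: `probe_id`, `t_stat`, `direction`,
#'   `p`, `max_fc`, `pass`.
#' @export
prefilter_probes <- function(exprs, p_threshold = 0.05, fc_threshold = 1.5,
                             B = 999L, seed = 1L) {
  stopifnot(inherits(exprs, "txpod_exprs"))
  if (B < 99L) config_error("B must be >= 99")
  values <- exprs$log2cpm
  gi <- group_index(exprs$design)
  perms <- make_perms(ncol(values), B, seed)
  res <- cpp_williams(values, gi - 1L, perms)

  # flat probes: t = 0 by construction, force p = 1
  flat <- apply(values, 1L, function(v) all(v == v[1]))
  p_up <- (1 + res$ge_up) / (B + 1)
  p_down <- (1 + res$ge_down) / (B + 1)
  p <- pmin(1, 2 * pmin(p_up, p_down))
  p[flat] <- 1
  up_better <- res$t_up >= res$t_down
  t_stat <- ifelse(up_better, res$t_up, res$t_down)
  t_stat[flat] <- 0

  gmeans <- t(apply(values, 1L, function(v) tapply(v, gi, mean)))
  max_fc <- 2^apply(abs(gmeans[, -1, drop = FALSE] - gmeans[, 1]), 1L, max)

  table <- data.frame(
    probe_id = rownames(values),
    t_stat = t_stat,
    direction = ifelse(up_better, "up", "down"),
    p = p, max_fc = max_fc,
    pass = p < p_threshold & max_fc >= fc_threshold,
    stringsAsFactors = FALSE)
  rownames(table) <- NULL
  list(pass = table$probe_id[table$pass], table = table)
}
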