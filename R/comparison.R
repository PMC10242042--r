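# Comparison of NAM-based administered equivalent doses with apical in vivo
# points of departure: lowest-AED selection per track, the log10-ratio
# outlier statistic, and cross-method/cross-track concordance summaries.

BMC_TRACK_METHODS <- c("p5", "mode1", "rank25", "lcrd")

#' Select the apical POD for a chemical
#'
#' The minimum effect level across all study types and method labels for
#' the CASRN; ties keep the first row by input order (logged via a
#' `tie` flag).
#'
#' @param apical a `txpod_apical_table` (from [read_reference_tables()]).
#' @param casrn chemical CASRN.
#' @return list with `pod` (mg/kg-bw/day), `study_type`, `method`, `tie`;
#'   or `NULL` (with a message) when the chemical has no rows.
#' @export
select_apical_pod <- function(apical, casrn) {
  rows <- apical[apical$casrn == casrn, , drop = FALSE]
  if (nrow(rows) == 0L) {
    message(sprintf("no apical POD for %s; excluded from comparison", casrn))
    return(NULL)
  }
  i <- which.min(rows$effect_level)
  tie <- sum(rows$effect_level == rows$effect_level[i]) > 1L
  if (tie) message(sprintf("apical POD tie for %s; first row kept", casrn))
  list(pod = rows$effect_level[i], study_type = rows$study_type[i],
       method = rows$method[i], tie = tie)
}

#' Select the lowest AED per chemical within a track
#'
#' The "bmc-distribution" track pools the four distribution methods (p5,
#' mode1, rank25, lcrd) across a chemical's experiments; the "gene-set"
#' track pools the gene-set AEDs. Provenance (method, experiment) of each
#' minimum is recorded so the tallies of which method supplied the minimum
#' are reproducible.
#'
#' @param aed_records data.frame with columns `casrn`, `method`,
#'   `experiment`, `aed` (one row per defined AED).
#' @param track `"bmc-distribution"` or `"gene-set"`.
#' @return data.frame with one row per chemical present in the track:
#'   `casrn`, `aed`, `method`, `experiment`.
#' @export
select_lowest_aed <- function(aed_records, track = c("bmc-distribution",
                                                     "gene-set")) {
  track <- match.arg(track)
  methods <- if (track == "bmc-distribution") BMC_TRACK_METHODS else "geneset"
  rec <- aed_records[aed_records$method %in% methods & !is.na(aed_records$aed),
                     , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(casrn = character(0), aed = numeric(0),
                      method = character(0), experiment = character(0),
                      stringsAsFactors = FALSE))
  }
  rec <- rec[order(rec$aed), , drop = FALSE]
  out <- rec[!duplicated(rec$casrn), c("casrn", "aed", "method", "experiment"),
             drop = FALSE]
  out$track <- track
  rownames(out) <- NULL
  out
}

#' Log10 ratio of apical POD to NAM-based AED
#'
#' \eqn{\mathrm{Log_{10}Ratio} = \log_{10}(POD_{Traditional}) -
#' \log_{10}(AED_{NAM})}; a negative ratio flags the chemical as an
#' outlier whose NAM-based estimate is less conservative than the
#' animal-derived POD.
#'
#' @param pod apical POD, mg/kg-bw/day (> 0).
#' @param aed NAM-based AED, mg/kg-bw/day (> 0).
#' @return list with `log10_ratio` and `outlier` (ratio < 0).
#' @export
log10_ratio <- function(pod, aed) {
  if (any(!is.finite(pod) | pod <= 0) || any(!is.finite(aed) | aed <= 0)) {
    data_error("POD and AED must both be positive")
  }
  ratio <- log10(pod) - log10(aed)
  list(log10_ratio = ratio, outlier = ratio < 0)
}

#' Build per-chemical comparison records for one track
#'
#' @param lowest_aeds a [select_lowest_aed()] result.
#' @param apical a `txpod_apical_table`.
#' @return data.frame of comparison records: `casrn`, `track`, `aed`,
#'   `aed_method`, `pod`, `pod_study_type`, `pod_method`, `log10_ratio`,
#'   `outlier`. Chemicals lacking an apical POD are omitted here and
#'   accounted for in the coverage table.
#' @export
compare_to_apical <- function(lowest_aeds, apical) {
  rows <- lapply(seq_len(nrow(lowest_aeds)), function(i) {
    sel <- suppressMessages(select_apical_pod(apical, lowest_aeds$casrn[i]))
    if (is.null(sel)) return(NULL)
    r <- log10_ratio(sel$pod, lowest_aeds$aed[i])
    data.frame(casrn = lowest_aeds$casrn[i], track = lowest_aeds$track[i],
               aed = lowest_aeds$aed[i], aed_method = lowest_aeds$method[i],
               pod = sel$pod, pod_study_type = sel$study_type,
               pod_method = sel$method, log10_ratio = r$log10_ratio,
               outlier = r$outlier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(casrn = character(0), track = character(0),
                      aed = numeric(0), aed_method = character(0),
                      pod = numeric(0), pod_study_type = character(0),
                      pod_method = character(0), log10_ratio = numeric(0),
                      outlier = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cross-method and cross-track concordance summary
#'
#' @param spreads named numeric vector of per-chemical log10 min-max tPOD
#'   spreads (NA allowed).
#' @param tpods named numeric vector of per-chemical representative tPODs
#'   (µM), used for the median log10 tPOD; may be NULL.
#' @param lowest_bmc,lowest_geneset [select_lowest_aed()] results for the
#'   two tracks.
#' @return list with `median_spread`, `median_log10_tpod`, `pearson_r`
#'   (log10 AEDs across chemicals present in both tracks; NA with fewer
#'   than 3 shared chemicals), `n_shared`, `within_1_order`,
#'   `within_2_orders` (counts of shared chemicals within ±1 / ±2 log10 of
#'   the identity line).
#' @export
concordance_summary <- function(spreads, tpods = NULL, lowest_bmc,
                                lowest_geneset) {
  shared <- intersect(lowest_bmc$casrn, lowest_geneset$casrn)
  r <- NA_real_; w1 <- NA_integer_; w2 <- NA_integer_
  if (length(shared) > 0L) {
    a <- log10(lowest_bmc$aed[match(shared, lowest_bmc$casrn)])
    b <- log10(lowest_geneset$aed[match(shared, lowest_geneset$casrn)])
    if (length(shared) >= 3L) r <- stats::cor(a, b, method = "pearson")
    w1 <- sum(abs(a - b) <= 1)
    w2 <- sum(abs(a - b) <= 2)
  }
  list(median_spread = median(spreads, na.rm = TRUE),
       median_log10_tpod = if (is.null(tpods)) NA_real_ else
         median(log10(tpods), na.rm = TRUE),
       pearson_r = r, n_shared = length(shared),
       within_1_order = w1, within_2_orders = w2)
}
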