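# The five tPOD summaries of a gene-level BMC distribution: fifth
# percentile (floor-index rule), first mode of the log10 kernel density,
# 25th ranked gene, modified lowest consistent response dose (largest
# consecutive-ratio group), and lowest gene-set median.

tpod_result <- function(method, value = NA_real_, n_genes = 0L,
                        active = !is.na(value), flag = NA_character_,
                        geneset_db = NA_character_, geneset_id = NA_character_,
                        geneset_members = NA_integer_) {
  structure(list(method = method, value = value, n_genes = as.integer(n_genes),
                 active = active, flag = flag, geneset_db = geneset_db,
                 geneset_id = geneset_id, geneset_members = geneset_members),
            class = "txpod_tpod")
}

#' @export
print.txpod_tpod <- function(x, ...) {
  cat(sprintf("<tPOD %s> %s (n_genes = %d%s)\n", x$method,
              if (x$active) sprintf("%g uM", x$value) else "inactive",
              x$n_genes,
              if (!is.na(x$geneset_id)) paste0(", set ", x$geneset_id) else ""))
  invisible(x)
}

#' Fifth-percentile tPOD
#'
#' Sorts the BMCs ascending and takes the value at 1-based rank
#' `max(1, floor(0.05 * n))` — the floor-index form of the fifth
#' percentile. With fewer than 20 BMCs the rank clamps to 1, i.e. the
#' lowest BMC. An interpolated percentile is available via
#' `interpolate = TRUE`.
#'
#' @param bmcs numeric vector of gene-level BMCs (µM).
#' @param prob percentile (default 0.05).
#' @param interpolate use `quantile(type = 7)` instead of the floor rule.
#' @return a tPOD result (method "p5").
#' @export
tpod_fifth_percentile <- function(bmcs, prob = 0.05, interpolate = FALSE) {
  bmcs <- bmcs[!is.na(bmcs)]
  n <- length(bmcs)
  if (n < 1L) return(tpod_result("p5", flag = "no BMCs"))
  value <- if (interpolate) {
    unname(quantile(bmcs, prob, type = 7))
  } else {
    sort(bmcs)[max(1L, floor(prob * n))]
  }
  tpod_result("p5", value, n)
}

#' First-mode tPOD
#'
#' Gaussian kernel density of log10(BMC) with Silverman's bandwidth on a
#' uniform grid spanning the data range plus one bandwidth on each side.
#' First and second derivatives are estimated by finite differences
#' (centered in the interior, forward/backward at the boundaries); the
#' first mode is the first grid point where the first derivative crosses
#' from positive to negative with a negative second derivative. A monotone
#' density (no such crossing) falls back to the boundary maximum, flagged.
#'
#' @param bmcs gene-level BMCs (µM).
#' @param grid_points density grid size (default 512).
#' @param min_genes minimum BMC count to attempt the mode (default 5).
#' @return a tPOD result (method "mode1").
#' @export
tpod_first_mode <- function(bmcs, grid_points = 512L, min_genes = 5L) {
  bmcs <- bmcs[!is.na(bmcs)]
  n <- length(bmcs)
  if (n < min_genes) return(tpod_result("mode1", n_genes = n,
                                        flag = "fewer genes than required"))
  lx <- log10(bmcs)
  if (diff(range(lx)) == 0) {
    return(tpod_result("mode1", 10^lx[1], n, flag = "degenerate (single value)"))
  }
  den <- density(lx, bw = "nrd0", n = grid_points, cut = 1)
  f <- den$y; x <- den$x; m <- length(x)
  h <- x[2] - x[1]
  d1 <- c((f[2] - f[1]) / h,
          (f[3:m] - f[1:(m - 2)]) / (2 * h),
          (f[m] - f[m - 1]) / h)
  d2 <- c((f[3] - 2 * f[2] + f[1]) / h^2,
          (f[3:m] - 2 * f[2:(m - 1)] + f[1:(m - 2)]) / h^2,
          (f[m] - 2 * f[m - 1] + f[m - 2]) / h^2)
  crossing <- which(d1[-m] > 0 & d1[-1] <= 0 & d2[-m] < 0)
  if (length(crossing) == 0L) {
    i <- which.max(f)  # monotone density: boundary maximum, flagged
    return(tpod_result("mode1", 10^x[i], n, flag = "monotone density"))
  }
  i <- crossing[1]
  # place the mode at the grid point with the larger density of the pair
  i <- if (f[i + 1] > f[i]) i + 1L else i
  tpod_result("mode1", 10^x[i], n)
}

#' N-th ranked gene tPOD
#'
#' The BMC of the `n_rank`-th lowest gene (1-based). Chemicals with fewer
#' than `n_rank` genes are inactive under this method.
#'
#' @param bmcs gene-level BMCs (µM).
#' @param n_rank rank threshold (default 25).
#' @return a tPOD result (method "rank25").
#' @export
tpod_nth_ranked <- function(bmcs, n_rank = 25L) {
  bmcs <- bmcs[!is.na(bmcs)]
  n <- length(bmcs)
  if (n < n_rank) return(tpod_result("rank25", n_genes = n,
                                     flag = "fewer genes than rank"))
  tpod_result("rank25", sort(bmcs)[n_rank], n)
}

# partition sorted BMCs into maximal runs where each consecutive ratio is
# within `ratio`; returns a grouping index vector
crgb_groups <- function(sorted_bmcs, ratio) {
  n <- length(sorted_bmcs)
  if (n == 0L) return(integer(0))
  breaks <- c(FALSE, sorted_bmcs[-1] / sorted_bmcs[-n] > ratio)
  cumsum(breaks) + 1L
}

#' Modified LCRD tPOD
#'
#' BMCs are sorted ascending and chained into consistent response groups
#' (CRGBs): maximal runs in which every consecutive ratio
#' \eqn{BMC_{i+1}/BMC_i} is within `ratio` (default 1.66). The modified
#' lowest consistent response dose is the minimum BMC of the *largest*
#' group, which discards small isolated groups of unrealistically low BMCs.
#' Size ties go to the group with the smaller minimum BMC.
#'
#' @param bmcs gene-level BMCs (µM).
#' @param ratio consecutive-ratio threshold (default 1.66).
#' @return a tPOD result (method "lcrd").
#' @export
tpod_lcrd <- function(bmcs, ratio = 1.66) {
  bmcs <- sort(bmcs[!is.na(bmcs)])
  n <- length(bmcs)
  if (n < 2L) return(tpod_result("lcrd", n_genes = n,
                                 flag = "fewer than 2 BMCs"))
  grp <- crgb_groups(bmcs, ratio)
  sizes <- tabulate(grp)
  mins <- vapply(split(bmcs, grp), min, numeric(1))
  best <- which(sizes == max(sizes))
  winner <- best[which.min(mins[best])]
  tpod_result("lcrd", mins[[winner]], n)
}

#' Lowest gene-set tPOD
#'
#' Across one or more gene-set collections, a set qualifies when at least
#' `min_genes` of its members have a BMC and those members represent at
#' least `min_frac` of the set's annotated size. Each qualifying set is
#' scored by the median of its members' BMCs; the tPOD is the minimum
#' median across all qualifying sets of all collections, with the winning
#' database and set recorded.
#'
#' @param gene_bmcs named numeric vector: gene id -> BMC (µM).
#' @param collections a [read_gene_sets()] object or list of them.
#' @param min_genes minimum members with a BMC (default 3).
#' @param min_frac minimum fraction of the annotated set size (default 0.05).
#' @return a tPOD result (method "geneset").
#' @export
tpod_lowest_gene_set <- function(gene_bmcs, collections, min_genes = 3L,
                                 min_frac = 0.05) {
  if (inherits(collections, "txpod_genesets")) collections <- list(collections)
  gene_bmcs <- gene_bmcs[!is.na(gene_bmcs)]
  best <- NULL
  for (coll in collections) {
    for (sid in names(coll$sets)) {
      hits <- intersect(coll$sets[[sid]], names(gene_bmcs))
      if (length(hits) < min_genes) next
      if (length(hits) / coll$sizes[[sid]] < min_frac) next
      med <- median(gene_bmcs[hits])
      if (is.null(best) || med < best$value) {
        best <- list(value = med, db = coll$database_label, id = sid,
                     members = length(hits))
      }
    }
  }
  if (is.null(best)) {
    return(tpod_result("geneset", n_genes = length(gene_bmcs),
                       flag = "no qualifying gene set"))
  }
  tpod_result("geneset", best$value, length(gene_bmcs),
              geneset_db = best$db, geneset_id = best$id,
              geneset_members = best$members)
}

#' Derive all five tPODs and the min-max spread
#'
#' @param gene_bmcs named numeric vector: gene id -> BMC (µM).
#' @param collections gene-set collection(s) for the gene-set method; may be
#'   `NULL` (the gene-set tPOD is then inactive).
#' @param config optional list overriding method parameters: `p5_prob`,
#'   `p5_interpolate`, `mode_grid_points`, `mode_min_genes`, `n_rank`,
#'   `lcrd_ratio`, `geneset_min_genes`, `geneset_min_frac`.
#' @return list with `results` (named list of the five tPOD results) and
#'   `spread`, the log10 difference between the highest and lowest defined
#'   tPOD (NA with fewer than two defined).
#' @export
derive_all <- function(gene_bmcs, collections = NULL, config = list()) {
  cfg <- function(key, default) config[[key]] %||% default
  results <- list(
    p5 = tpod_fifth_percentile(gene_bmcs, cfg("p5_prob", 0.05),
                               cfg("p5_interpolate", FALSE)),
    mode1 = tpod_first_mode(gene_bmcs, cfg("mode_grid_points", 512L),
                            cfg("mode_min_genes", 5L)),
    rank25 = tpod_nth_ranked(gene_bmcs, cfg("n_rank", 25L)),
    lcrd = tpod_lcrd(gene_bmcs, cfg("lcrd_ratio", 1.66)),
    geneset = if (is.null(collections)) {
      tpod_result("geneset", n_genes = sum(!is.na(gene_bmcs)),
                  flag = "no collections supplied")
    } else {
      tpod_lowest_gene_set(gene_bmcs, collections,
                           cfg("geneset_min_genes", 3L),
                           cfg("geneset_min_frac", 0.05))
    })
  defined <- vapply(results, function(r) if (r$active) r$value else NA_real_,
                    numeric(1))
  defined <- defined[!is.na(defined)]
  spread <- if (length(defined) >= 2L) {
    log10(max(defined)) - log10(min(defined))
  } else NA_real_
  list(results = results, spread = spread)
}

#' Flatten tPOD results to a tidy table
#'
#' @param derived a [derive_all()] result.
#' @param chemical_id,cell_model,exposure_days experiment labels to attach.
#' @return data.frame: chemical, cell_model, exposure_days, method,
#'   tpod_uM, n_genes, active, geneset_db, geneset_id.
#' @export
tpod_table <- function(derived, chemical_id = NA, cell_model = NA,
                       exposure_days = NA) {
  rows <- lapply(derived$results, function(r) {
    data.frame(chemical = chemical_id, cell_model = cell_model,
               exposure_days = exposure_days, method = r$method,
               tpod_uM = if (r$active) r$value else NA_real_,
               n_genes = r$n_genes, active = r$active,
               geneset_db = r$geneset_db, geneset_id = r$geneset_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
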