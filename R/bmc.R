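# Benchmark-concentration derivation from a selected model fit: inversion at
# a benchmark response of bmr_k standard deviations, profile-likelihood
# confidence bounds, post-filters, and probe-to-gene collapse.

#' Invert a fitted model at the benchmark response
#'
#' The BMC is the smallest concentration in (0, c_top] at which the modeled
#' mean departs from the control mean by `bmr_k` times the fitted residual
#' standard deviation (two-sided, first crossing), located by sign
#' bracketing on a log-spaced grid followed by bisection to a relative
#' tolerance of 1e-6.
#'
#' @param fit a converged fit from [fit_family()]/[select_model()].
#' @param bmr_k benchmark response in standard deviations (default 1).
#' @param c_top highest tested concentration (µM).
#' @param c_min lowest nonzero tested concentration; when given, BMCs below
#'   it are flagged as extrapolated.
#' @return list with `bmc` (µM or NA), `extrapolated` flag, and `reason`
#'   (NA or why the BMC is undefined).
#' @export
bmc_from_fit <- function(fit, bmr_k = 1, c_top, c_min = NULL) {
  if (is.null(fit) || !isTRUE(fit$converged)) {
    return(list(bmc = NA_real_, extrapolated = FALSE, reason = "no converged fit"))
  }
  if (!is.finite(fit$sigma) || fit$sigma <= 0) {
    txpod_error("txpod_model_error", "fitted sigma is zero; BMR of k*SD is undefined")
  }
  mu0 <- predict_mu(fit, 0)
  target <- bmr_k * fit$sigma
  f <- function(c) abs(predict_mu(fit, c) - mu0) - target
  grid <- 10^seq(log10(c_top) - 10, log10(c_top), length.out = 400L)
  fv <- f(grid)
  if (all(fv < 0)) {
    return(list(bmc = NA_real_, extrapolated = FALSE, reason = "no BMC <= top"))
  }
  i <- which(fv >= 0)[1]
  bmc <- if (i == 1L) {
    grid[1]  # response already past the benchmark at the bottom of the grid
  } else if (fv[i] == 0) {
    grid[i]
  } else {
    uniroot(function(lc) f(10^lc), c(log10(grid[i - 1]), log10(grid[i])),
            tol = 1e-7)$root -> lr
    10^lr
  }
  extrap <- !is.null(c_min) && bmc < c_min
  list(bmc = bmc, extrapolated = extrap, reason = NA_character_)
}

# negative profile log-likelihood at candidate BMC `b`: maximize over the
# nuisance parameters with one mean parameter substituted so that
# |mu(b) - mu(0)| = bmr_k * sigma holds exactly. `dir` is the sign of
# mu(bmc) - mu(0) at the fitted optimum.
profile_negll <- function(fit, b, bmr_k, dir) {
  conc <- fit$conc; y <- fit$y; n <- length(y)
  k <- bmr_k
  BIG <- 1e10
  nll <- function(mu, sig) {
    if (any(!is.finite(mu))) return(BIG)
    n / 2 * log(2 * pi * sig^2) + sum((y - mu)^2) / (2 * sig^2)
  }
  fam <- fit$family
  s <- fit$s %||% dir
  obj <- switch(fam,
    linear = function(par) {
      sig <- exp(par[2])
      nll(par[1] + (dir * k * sig / b) * conc, sig)
    },
    poly2 = function(par) {
      sig <- exp(par[3])
      b1 <- (dir * k * sig - par[2] * b^2) / b
      nll(par[1] + b1 * conc + par[2] * conc^2, sig)
    },
    power = function(par) {
      sig <- exp(par[3]); d <- par[2]
      nll(par[1] + (dir * k * sig / b^d) * conc^d, sig)
    },
    exp2 = function(par) {
      sig <- exp(par[2]); a <- exp(par[1]); q <- k * sig / a
      if (s > 0) br <- log1p(q) / b
      else { if (q >= 1) return(BIG); br <- -log(1 - q) / b }
      nll(a * exp(s * br * conc), sig)
    },
    exp3 = function(par) {
      sig <- exp(par[3]); a <- exp(par[1]); d <- par[2]; q <- k * sig / a
      if (s > 0) arg <- log1p(q)
      else { if (q >= 1) return(BIG); arg <- -log(1 - q) }
      br <- arg^(1 / d) / b
      nll(a * exp(s * pmin((br * conc)^d, 500)), sig)
    },
    exp4 = function(par) {
      sig <- exp(par[3]); a <- exp(par[1])
      kp <- if (s > 0) 1 + exp(par[2]) else 1 / (1 + exp(-par[2]))
      q <- k * sig / (a * abs(kp - 1))
      if (!is.finite(q) || q >= 1) return(BIG)
      br <- -log(1 - q) / b
      nll(a * (kp - (kp - 1) * exp(-br * conc)), sig)
    },
    exp5 = function(par) {
      sig <- exp(par[4]); a <- exp(par[1]); d <- par[3]
      kp <- if (s > 0) 1 + exp(par[2]) else 1 / (1 + exp(-par[2]))
      q <- k * sig / (a * abs(kp - 1))
      if (!is.finite(q) || q >= 1) return(BIG)
      br <- (-log(1 - q))^(1 / d) / b
      nll(a * (kp - (kp - 1) * exp(-pmin((br * conc)^d, 500))), sig)
    })
  p <- fit$params
  ls <- log(fit$sigma)
  start <- switch(fam,
    linear = c(p[["b0"]], ls),
    poly2  = c(p[["b0"]], p[["b2"]], ls),
    power  = c(p[["g"]], max(1, min(POWER_D_MAX, p[["d"]])), ls),
    exp2   = c(log(p[["a"]]), ls),
    exp3   = c(log(p[["a"]]), max(1, min(POWER_D_MAX, p[["d"]])), ls),
    exp4   = c(log(p[["a"]]),
               if (s > 0) log(max(p[["k"]] - 1, 1e-6))
               else log(p[["k"]] / max(1 - p[["k"]], 1e-6)), ls),
    exp5   = c(log(p[["a"]]),
               if (s > 0) log(max(p[["k"]] - 1, 1e-6))
               else log(p[["k"]] / max(1 - p[["k"]], 1e-6)),
               max(1, min(POWER_D_MAX, p[["d"]])), ls))
  lower <- rep(-Inf, length(start)); upper <- rep(Inf, length(start))
  if (fam %in% c("power", "exp3")) { lower[2] <- 1; upper[2] <- POWER_D_MAX }
  if (fam == "exp5") { lower[3] <- 1; upper[3] <- POWER_D_MAX }
  opt <- tryCatch(
    nlminb(start, obj, lower = lower, upper = upper,
           control = list(iter.max = MAX_ITER)),
    error = function(e) NULL)
  if (is.null(opt)) return(BIG)
  opt$objective
}

#' Profile-likelihood confidence bounds on the BMC
#'
#' Each bound sits where the profile deviance
#' \eqn{2(\hat\ell - \ell_{prof})} reaches \eqn{\chi^2_1(0.90) = 2.706},
#' giving one-sided 95% coverage per bound for `conf = 0.95` (the BMDS
#' convention). The search is bounded to `[c_top * 1e-6, c_top * 1e3]`; a
#' bound that never crosses within the search range is set to the search
#' limit and flagged.
#'
#' @param fit the selected fit (with data attached, as from [fit_family()]).
#' @param bmc the BMC from [bmc_from_fit()].
#' @param conf nominal two-sided confidence level (default 0.95).
#' @param bmr_k benchmark response in SDs used for the BMC.
#' @param c_top highest tested concentration.
#' @return list with `bmcl`, `bmcu`, `bounded_l`, `bounded_u` flags, or
#'   `reason` when the profile fails.
#' @export
profile_bounds <- function(fit, bmc, conf = 0.95, bmr_k = 1, c_top = NULL) {
  if (is.null(c_top)) c_top <- max(fit$conc)
  crit <- qchisq(1 - 2 * (1 - conf), df = 1)
  mu0 <- predict_mu(fit, 0)
  dir <- if (predict_mu(fit, bmc) - mu0 >= 0) 1 else -1
  ll_at <- function(c) -profile_negll(fit, c, bmr_k, dir)
  ll_hat <- max(fit$loglik, ll_at(bmc))
  g <- function(lc) 2 * (ll_hat - ll_at(10^lc)) - crit
  lim_l <- log10(c_top * 1e-6); lim_u <- log10(c_top * 1e3)
  lb <- log10(bmc)
  out <- tryCatch({
    g_bmc <- g(lb)
    if (g_bmc > 0) {
      # profile optimum displaced from the point estimate beyond the
      # critical drop: cannot anchor the bracket
      return(list(bmcl = NA_real_, bmcu = NA_real_, reason = "CI failure"))
    }
    if (lb <= lim_l) {
      bmcl <- 10^lim_l; bl <- FALSE
    } else if (g(lim_l) < 0) {
      bmcl <- 10^lim_l; bl <- FALSE
    } else {
      bmcl <- 10^uniroot(g, c(lim_l, lb), tol = 1e-6)$root; bl <- TRUE
    }
    if (lb >= lim_u) {
      bmcu <- 10^lim_u; bu <- FALSE
    } else if (g(lim_u) < 0) {
      bmcu <- 10^lim_u; bu <- FALSE
    } else {
      bmcu <- 10^uniroot(g, c(lb, lim_u), tol = 1e-6)$root; bu <- TRUE
    }
    list(bmcl = min(bmcl, bmc), bmcu = max(bmcu, bmc),
         bounded_l = bl, bounded_u = bu, reason = NA_character_)
  }, error = function(e) list(bmcl = NA_real_, bmcu = NA_real_,
                              reason = "CI failure"))
  out
}

#' Apply the BMC post-filters
#'
#' A record is dropped iff its goodness-of-fit p-value is below 0.1, its
#' BMCU/BMCL ratio exceeds 40, or its BMC exceeds the highest tested
#' concentration (all rules strict as stated: `p < 0.1`, `ratio > 40`,
#' `bmc > c_top`). Records already marked dropped (no BMC, CI failure) stay
#' dropped.
#'
#' @param records data.frame of BMC records (from [fit_bmc()]).
#' @param c_top highest tested concentration (µM).
#' @param fit_p_min,ci_ratio_max filter thresholds (defaults 0.1 and 40).
#' @return the retained subset; the dropped rows, with a `drop_reason`
#'   column, are attached as `attr(, "dropped")`.
#' @export
postfilter_records <- function(records, c_top, fit_p_min = 0.1,
                               ci_ratio_max = 40) {
  reason <- rep(NA_character_, nrow(records))
  pre <- !is.na(records$drop_reason)
  reason[pre] <- records$drop_reason[pre]
  candidate <- !pre
  bad_p <- candidate & records$fit_p < fit_p_min
  reason[bad_p & is.na(reason)] <- sprintf("fit p < %g", fit_p_min)
  bad_ci <- candidate & !is.na(records$bmcl) & !is.na(records$bmcu) &
    records$bmcu / records$bmcl > ci_ratio_max
  reason[bad_ci & is.na(reason)] <- sprintf("BMCU/BMCL > %g", ci_ratio_max)
  bad_top <- candidate & records$bmc > c_top
  reason[bad_top & is.na(reason)] <- "BMC > top concentration"
  keep <- is.na(reason)
  retained <- records[keep, , drop = FALSE]
  dropped <- records[!keep, , drop = FALSE]
  dropped$drop_reason <- reason[!keep]
  rownames(retained) <- rownames(dropped) <- NULL
  attr(retained, "dropped") <- dropped
  retained
}

#' Collapse probe-level BMC records to genes
#'
#' When several retained probes map to one gene, the gene inherits the BMC,
#' BMCL and BMCU of the probe with the lowest BMC. Probes absent from the
#' map are excluded with a warning.
#'
#' @param records retained probe-level records.
#' @param probe_map named character vector, probe id -> gene id.
#' @return gene-level data.frame with `gene_id` plus the winning probe's
#'   columns, sorted by BMC.
#' @export
collapse_to_genes <- function(records, probe_map) {
  if (nrow(records) == 0L) {
    return(cbind(gene_id = character(0), records))
  }
  mapped <- records$probe_id %in% names(probe_map)
  if (any(!mapped)) {
    warning(sprintf("%d probe(s) not in the probe map were excluded: %s",
                    sum(!mapped),
                    paste(utils::head(records$probe_id[!mapped], 5),
                          collapse = ", ")))
  }
  records <- records[mapped, , drop = FALSE]
  records$gene_id <- unname(probe_map[records$probe_id])
  records <- records[order(records$bmc), , drop = FALSE]
  out <- records[!duplicated(records$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene_id", setdiff(names(out), "gene_id"))]
}

#' Fit BMC models for a set of probes in one experiment
#'
#' Runs [fit_family()], [select_model()], [bmc_from_fit()] and
#' [profile_bounds()] per probe and assembles the probe-level BMC record
#' table. Probes whose modeling fails at any stage appear with a
#' `drop_reason` so attrition is visible; [postfilter_records()] then
#' applies the statistical post-filters.
#'
#' @param exprs a [normalize_log2cpm()] result.
#' @param probes probe ids to model (typically the prefilter pass-set).
#' @param bmr_k,conf,alpha_nested modeling parameters: benchmark response in
#'   SDs, bound confidence level, nested-test alpha.
#' @return data.frame with one row per probe: `probe_id`, `chemical_id`,
#'   `family`, `params` (compact "name=value" string), `sigma`, `fit_p`,
#'   `bmc`, `bmcl`, `bmcu`, `extrapolated`, `drop_reason`.
#' @export
fit_bmc <- function(exprs, probes, bmr_k = 1, conf = 0.95,
                    alpha_nested = 0.05) {
  stopifnot(inherits(exprs, "txpod_exprs"))
  conc <- exprs$design$concentration_uM
  c_top <- max(conc); c_min <- min(conc[conc > 0])
  rows <- lapply(probes, function(pid) {
    y <- exprs$log2cpm[pid, ]
    base <- data.frame(probe_id = pid, chemical_id = exprs$chemical_id,
                       family = NA_character_, params = NA_character_,
                       sigma = NA_real_, fit_p = NA_real_, bmc = NA_real_,
                       bmcl = NA_real_, bmcu = NA_real_,
                       extrapolated = FALSE, drop_reason = NA_character_,
                       stringsAsFactors = FALSE)
    fits <- fit_family(conc, y)
    best <- select_model(fits, alpha_nested)
    if (is.null(best)) {
      base$drop_reason <- "no converged fit"
      return(base)
    }
    base$family <- best$family
    base$params <- paste(sprintf("%s=%.6g", names(best$params), best$params),
                         collapse = ";")
    base$sigma <- best$sigma
    base$fit_p <- best$fit_p
    if (best$sigma <= 0) {
      base$drop_reason <- "zero residual SD"
      return(base)
    }
    inv <- bmc_from_fit(best, bmr_k, c_top, c_min)
    if (is.na(inv$bmc)) {
      base$drop_reason <- inv$reason
      return(base)
    }
    base$bmc <- inv$bmc
    base$extrapolated <- inv$extrapolated
    pb <- profile_bounds(best, inv$bmc, conf, bmr_k, c_top)
    if (!is.na(pb$reason %||% NA_character_)) {
      base$drop_reason <- pb$reason
      return(base)
    }
    base$bmcl <- pb$bmcl
    base$bmcu <- pb$bmcu
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
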