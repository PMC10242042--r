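# Continuous dose-response model family and best-model selection.
#
# Seven families are fit to per-sample log2 CPM responses by maximum
# likelihood under a normal constant-variance error model (equivalently,
# least squares with sigma^2 = RSS/n):
#   Linear  mu = b0 + b1 c
#   Poly2   mu = b0 + b1 c + b2 c^2
#   Power   mu = g + b c^d,              d in [1, 18]
#   Exp2    mu = a exp(s b c),           a > 0, b > 0, s = +/-1
#   Exp3    mu = a exp(s (b c)^d),       d in [1, 18]
#   Exp4    mu = a (k - (k - 1) exp(-b c))
#   Exp5    mu = a (k - (k - 1) exp(-(b c)^d))
# with k > 1 for increasing and 0 < k < 1 for decreasing responses in
# Exp4/Exp5. Exponential forms follow the EPA continuous-model family; the
# parameter constraints are config-visible here rather than buried in the
# optimizer. Nonlinear parameters are searched on deterministic coarse grids
# with the linear parameters profiled out exactly (OLS), then refined with
# nlminb (<= 250 iterations).

POWER_D_MAX <- 18
MAX_ITER <- 250L

fit_k_mean <- c(linear = 2L, poly2 = 3L, power = 3L, exp2 = 2L,
                exp3 = 3L, exp4 = 3L, exp5 = 4L)

#' Evaluate a fitted model's mean function
#'
#' @param fit a single model fit as returned by [fit_family()].
#' @param conc concentrations (µM) at which to evaluate.
#' @return numeric vector of modeled means.
#' @export
predict_mu <- function(fit, conc) {
  p <- fit$params
  switch(fit$family,
    linear = p["b0"] + p["b1"] * conc,
    poly2  = p["b0"] + p["b1"] * conc + p["b2"] * conc^2,
    power  = p["g"] + p["b"] * conc^p["d"],
    exp2   = p["a"] * exp(fit$s * p["b"] * conc),
    exp3   = p["a"] * exp(fit$s * (p["b"] * conc)^p["d"]),
    exp4   = p["a"] * (p["k"] - (p["k"] - 1) * exp(-p["b"] * conc)),
    exp5   = p["a"] * (p["k"] - (p["k"] - 1) * exp(-(p["b"] * conc)^p["d"])),
    stop("unknown family ", fit$family))
}

loglik_from_rss <- function(rss, n) {
  if (!is.finite(rss) || rss <= 0) rss <- max(rss, 1e-300)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# OLS of y on a design matrix; returns list(coef, rss) or NULL if singular
ols <- function(X, y) {
  fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

mk_fit <- function(family, params, s, rss, n, converged = TRUE) {
  ll <- loglik_from_rss(rss, n)
  k <- fit_k_mean[[family]]
  list(family = family, params = params, s = s, rss = rss, n = n,
       sigma = sqrt(max(rss, 0) / n), loglik = ll,
       aic = 2 * (k + 1) - 2 * ll, k_mean = k, converged = converged)
}

fit_linear <- function(conc, y) {
  o <- ols(cbind(1, conc), y)
  if (is.null(o)) return(mk_fit("linear", c(b0 = NA, b1 = NA), NULL, Inf,
                                length(y), FALSE))
  mk_fit("linear", c(b0 = unname(o$coef[1]), b1 = unname(o$coef[2])), NULL,
         o$rss, length(y))
}

fit_poly2 <- function(conc, y) {
  o <- ols(cbind(1, conc, conc^2), y)
  if (is.null(o)) return(mk_fit("poly2", c(b0 = NA, b1 = NA, b2 = NA), NULL,
                                Inf, length(y), FALSE))
  mk_fit("poly2", c(b0 = unname(o$coef[1]), b1 = unname(o$coef[2]),
                    b2 = unname(o$coef[3])), NULL, o$rss, length(y))
}

fit_power <- function(conc, y) {
  rss_d <- function(d) {
    o <- ols(cbind(1, conc^d), y)
    if (is.null(o)) Inf else o$rss
  }
  d_grid <- exp(seq(log(1), log(POWER_D_MAX), length.out = 12))
  vals <- vapply(d_grid, rss_d, numeric(1))
  i <- which.min(vals)
  lo <- d_grid[max(1, i - 1)]; hi <- d_grid[min(length(d_grid), i + 1)]
  opt <- optimize(rss_d, c(lo, hi))
  d <- if (opt$objective < vals[i]) opt$minimum else d_grid[i]
  o <- ols(cbind(1, conc^d), y)
  if (is.null(o)) return(mk_fit("power", c(g = NA, b = NA, d = NA), NULL,
                                Inf, length(y), FALSE))
  mk_fit("power", c(g = unname(o$coef[1]), b = unname(o$coef[2]), d = d),
         NULL, o$rss, length(y))
}

# shared machinery for Exp2/Exp3: a * exp(s * (b c)^d), a profiled by OLS
# through the origin; d = 1 recovers Exp2
fit_exp23 <- function(conc, y, s, with_d) {
  c_top <- max(conc)
  rss_bd <- function(b, d) {
    arg <- s * (b * conc)^d
    if (any(arg > 500)) return(list(rss = Inf))
    x <- exp(arg)
    a <- sum(x * y) / sum(x * x)
    if (!is.finite(a) || a <= 0) return(list(rss = Inf))
    list(rss = sum((y - a * x)^2), a = a)
  }
  b_grid <- 10^seq(-3, 2, length.out = 26) / c_top
  d_grid <- if (with_d) c(1, 1.3, 1.7, 2.2, 3, 4.5, 7, 12, 18) else 1
  grid <- expand.grid(b = b_grid, d = d_grid)
  vals <- mapply(function(b, d) rss_bd(b, d)$rss, grid$b, grid$d)
  if (all(!is.finite(vals))) {
    fam <- if (with_d) "exp3" else "exp2"
    return(mk_fit(fam, setNames(rep(NA_real_, fit_k_mean[[fam]]),
                                if (with_d) c("a", "b", "d") else c("a", "b")),
                  s, Inf, length(y), FALSE))
  }
  i <- which.min(vals)
  if (with_d) {
    obj <- function(th) {
      r <- rss_bd(exp(th[1]), exp(th[2]))$rss
      if (!is.finite(r)) 1e10 else r
    }
    b <- grid$b[i]; d <- grid$d[i]; fbest <- vals[i]
    for (j in order(vals)[seq_len(min(3, sum(is.finite(vals))))]) {
      opt <- nlminb(c(log(grid$b[j]), log(grid$d[j])), obj,
                    lower = c(log(min(b_grid)) - 3, 0),
                    upper = c(log(max(b_grid)) + 3, log(POWER_D_MAX)),
                    control = list(iter.max = MAX_ITER))
      if (opt$objective < fbest) {
        fbest <- opt$objective
        b <- exp(opt$par[1]); d <- exp(opt$par[2])
      }
    }
    best <- rss_bd(b, d)
    mk_fit("exp3", c(a = best$a, b = b, d = d), s, best$rss, length(y))
  } else {
    obj <- function(th) {
      r <- rss_bd(exp(th), 1)$rss
      if (!is.finite(r)) 1e10 else r
    }
    opt <- nlminb(log(grid$b[i]), obj, lower = log(min(b_grid)) - 3,
                  upper = log(max(b_grid)) + 3,
                  control = list(iter.max = MAX_ITER))
    b <- if (opt$objective < vals[i]) exp(opt$par) else grid$b[i]
    best <- rss_bd(b, 1)
    mk_fit("exp2", c(a = best$a, b = b), s, best$rss, length(y))
  }
}

# shared machinery for Exp4/Exp5: mu = A + B exp(-(b c)^d) with A = a k,
# B = -a (k - 1); (A, B) profiled by OLS, constraints checked afterwards
fit_exp45 <- function(conc, y, s, with_d) {
  fam <- if (with_d) "exp5" else "exp4"
  pnames <- if (with_d) c("a", "b", "k", "d") else c("a", "b", "k")
  c_top <- max(conc)
  decomp <- function(b, d) {
    x <- exp(-pmin((b * conc)^d, 500))
    o <- ols(cbind(1, x), y)
    if (is.null(o)) return(list(rss = Inf))
    A <- unname(o$coef[1]); B <- unname(o$coef[2])
    a <- A + B
    if (!is.finite(a) || a <= 0) return(list(rss = Inf))
    k <- A / a
    # direction constraint: k > 1 increasing, 0 < k < 1 decreasing
    ok <- if (s > 0) k > 1 else (k > 0 && k < 1)
    if (!ok) return(list(rss = Inf))
    list(rss = o$rss, a = a, k = k)
  }
  b_grid <- 10^seq(-3, 2.5, length.out = 26) / c_top
  d_grid <- if (with_d) c(1, 1.3, 1.7, 2.2, 3, 4.5, 7, 12, 18) else 1
  grid <- expand.grid(b = b_grid, d = d_grid)
  vals <- mapply(function(b, d) decomp(b, d)$rss, grid$b, grid$d)
  if (all(!is.finite(vals))) {
    return(mk_fit(fam, setNames(rep(NA_real_, length(pnames)), pnames), s,
                  Inf, length(y), FALSE))
  }
  i <- which.min(vals)
  obj <- if (with_d) {
    function(th) {
      r <- decomp(exp(th[1]), exp(th[2]))$rss
      if (!is.finite(r)) 1e10 else r
    }
  } else {
    function(th) {
      r <- decomp(exp(th), 1)$rss
      if (!is.finite(r)) 1e10 else r
    }
  }
  if (with_d) {
    b <- grid$b[i]; d <- grid$d[i]; fbest <- vals[i]
    for (j in order(vals)[seq_len(min(3, sum(is.finite(vals))))]) {
      opt <- nlminb(c(log(grid$b[j]), log(grid$d[j])), obj,
                    lower = c(log(min(b_grid)) - 3, 0),
                    upper = c(log(max(b_grid)) + 3, log(POWER_D_MAX)),
                    control = list(iter.max = MAX_ITER))
      if (opt$objective < fbest) {
        fbest <- opt$objective
        b <- exp(opt$par[1]); d <- exp(opt$par[2])
      }
    }
  } else {
    opt <- nlminb(log(grid$b[i]), obj, lower = log(min(b_grid)) - 3,
                  upper = log(max(b_grid)) + 3,
                  control = list(iter.max = MAX_ITER))
    b <- if (opt$objective < vals[i]) exp(opt$par) else grid$b[i]
    d <- 1
  }
  best <- decomp(b, d)
  params <- c(a = best$a, b = b, k = best$k)
  if (with_d) params <- c(params, d = d)
  mk_fit(fam, params, s, best$rss, length(y))
}

# deviance goodness-of-fit against the saturated group-means model,
# df = #groups - #mean-parameters
fit_gof_p <- function(fit, conc, y) {
  gm <- tapply(y, conc, mean)
  rss_sat <- sum((y - gm[as.character(conc)])^2)
  ll_sat <- loglik_from_rss(rss_sat, length(y))
  df <- length(gm) - fit$k_mean
  if (df <= 0) return(1)
  stat <- max(0, 2 * (ll_sat - fit$loglik))
  pchisq(stat, df, lower.tail = FALSE)
}

#' Fit the continuous dose-response model family to one probe
#'
#' @param concentrations per-sample concentrations (µM, 0 = control).
#' @param responses per-sample responses (log2 CPM).
#' @return list of class `txpod_fits`: one fit per family (named
#'   `linear`, `poly2`, `power`, `exp2`, `exp3`, `exp4`, `exp5`), each with
#'   the parameter vector, direction `s`, `sigma`, `loglik`, `aic`,
#'   `fit_p` (goodness-of-fit vs the saturated group-means model) and a
#'   `converged` flag. The response direction (increasing/decreasing) is
#'   taken from the top-group mean relative to control.
#' @export
fit_family <- function(concentrations, responses) {
  conc <- as.numeric(concentrations); y <- as.numeric(responses)
  stopifnot(length(conc) == length(y))
  if (length(unique(conc)) < 6L) {
    design_error("at least 6 concentration groups (incl. control) are required for modeling")
  }
  gm <- tapply(y, conc, mean)
  s <- if (gm[[length(gm)]] >= gm[[1]]) 1 else -1
  fits <- list(
    linear = fit_linear(conc, y),
    poly2  = fit_poly2(conc, y),
    power  = fit_power(conc, y),
    exp2   = fit_exp23(conc, y, s, with_d = FALSE),
    exp3   = fit_exp23(conc, y, s, with_d = TRUE),
    exp4   = fit_exp45(conc, y, s, with_d = FALSE),
    exp5   = fit_exp45(conc, y, s, with_d = TRUE))
  for (nm in names(fits)) {
    fits[[nm]]$conc <- conc
    fits[[nm]]$y <- y
    fits[[nm]]$fit_p <- if (fits[[nm]]$converged) {
      fit_gof_p(fits[[nm]], conc, y)
    } else NA_real_
  }
  structure(fits, class = "txpod_fits")
}

#' Select the best-fit model
#'
#' Step 1: Poly2 is retained over Linear only if the nested chi-square test
#' (deviance on 1 df) rejects at `alpha_nested`. Step 2: the surviving
#' linear-family candidate competes with Power and Exp2-5 on lowest AIC.
#' Ties go to the model with fewer parameters, then to family order.
#' Non-converged fits never participate.
#'
#' @param fits a [fit_family()] result.
#' @param alpha_nested nested-test significance level (default 0.05).
#' @return the winning fit, or `NULL` if no fit converged.
#' @export
select_model <- function(fits, alpha_nested = 0.05) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0L) return(NULL)
  candidates <- conv
  if (all(c("linear", "poly2") %in% names(conv))) {
    dev <- max(0, 2 * (conv$poly2$loglik - conv$linear$loglik))
    p <- pchisq(dev, 1, lower.tail = FALSE)
    drop_fam <- if (p < alpha_nested) "linear" else "poly2"
    candidates <- candidates[setdiff(names(candidates), drop_fam)]
  }
  ord <- order(vapply(candidates, `[[`, numeric(1), "aic"),
               vapply(candidates, `[[`, integer(1), "k_mean"),
               match(names(candidates), names(fit_k_mean)))
  candidates[[ord[1]]]
}
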