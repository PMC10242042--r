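# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain-R PAVA by repeated merging, a
# loop-based Williams statistic, a from-scratch LCRD partitioner, and
# closed-form BMC inversions.

# weighted isotonic regression by repeated scanning (not the stack
# algorithm used in src/)
oracle_pava <- function(y, w) {
  blocks <- lapply(seq_along(y), function(i) list(v = y[i], w = w[i], n = 1L))
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(blocks)) {
      if (blocks[[i]]$v > blocks[[i + 1]]$v) {
        tw <- blocks[[i]]$w + blocks[[i + 1]]$w
        blocks[[i]] <- list(
          v = (blocks[[i]]$v * blocks[[i]]$w +
                 blocks[[i + 1]]$v * blocks[[i + 1]]$w) / tw,
          w = tw, n = blocks[[i]]$n + blocks[[i + 1]]$n)
        blocks[[i + 1]] <- NULL
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  unlist(lapply(blocks, function(b) rep(b$v, b$n)))
}

# Williams-type statistic, better direction, straight from the definition
oracle_williams_stat <- function(values, groups) {
  g <- sort(unique(groups))
  means <- vapply(g, function(k) mean(values[groups == k]), numeric(1))
  n_g <- vapply(g, function(k) sum(groups == k), numeric(1))
  rss <- sum(vapply(g, function(k) {
    v <- values[groups == k]; sum((v - mean(v))^2)
  }, numeric(1)))
  s2 <- rss / (length(values) - length(g))
  se <- sqrt(s2 * (1 / n_g[1] + 1 / n_g[length(g)]))
  t_dir <- function(m) {
    iso <- oracle_pava(m, n_g)
    (iso[length(iso)] - m[1]) / se
  }
  max(t_dir(means), t_dir(-means))
}

# LCRD from first principles: enumerate every break position, build groups,
# pick the largest (ties -> smallest minimum)
oracle_lcrd <- function(bmcs, ratio = 1.66) {
  x <- sort(bmcs)
  if (length(x) < 2L) return(NA_real_)
  groups <- list(x[1])
  for (i in 2:length(x)) {
    cur <- groups[[length(groups)]]
    if (x[i] / cur[length(cur)] <= ratio) {
      groups[[length(groups)]] <- c(cur, x[i])
    } else {
      groups[[length(groups) + 1L]] <- x[i]
    }
  }
  sizes <- lengths(groups)
  mins <- vapply(groups, min, numeric(1))
  cand <- which(sizes == max(sizes))
  min(mins[cand])
}

# closed-form BMC inversions for the oracle-equivalence checks
oracle_bmc_linear <- function(b1, sigma, k = 1) k * sigma / abs(b1)
oracle_bmc_exp2 <- function(a, b, s, sigma, k = 1) {
  # |a (e^{s b c} - 1)| = k sigma
  if (s > 0) log(1 + k * sigma / a) / b else -log(1 - k * sigma / a) / b
}

# small deterministic experiment builder: group means supplied per probe,
# Gaussian noise optional
make_exprs <- function(group_means, n_rep = 3, sd = 0,
                       conc = c(0, 10^seq(log10(5e-4), 2, length.out = 10)),
                       seed = 1) {
  set.seed(seed)
  stopifnot(ncol(group_means) == length(conc))
  design <- data.frame(
    sample_id = sprintf("s%02d_r%d", rep(seq_along(conc), each = n_rep),
                        rep(seq_len(n_rep), length(conc))),
    concentration_uM = rep(conc, each = n_rep),
    replicate = rep(seq_len(n_rep), length(conc)),
    stringsAsFactors = FALSE)
  vals <- group_means[, rep(seq_along(conc), each = n_rep), drop = FALSE] +
    matrix(rnorm(nrow(group_means) * nrow(design), 0, sd),
           nrow(group_means))
  rownames(vals) <- rownames(group_means) %||%
    sprintf("p%03d", seq_len(nrow(group_means)))
  colnames(vals) <- design$sample_id
  structure(list(log2cpm = vals, size_factors = rep(1, nrow(design)),
                 design = design, chemical_id = "test-chem"),
            class = "txpod_exprs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
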