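make_experiment_from_counts <- function(counts, n_rep = 3,
                                        conc = c(0, 10^seq(-3, 2,
                                                           length.out = 10))) {
  design <- data.frame(
    sample_id = colnames(counts),
    concentration_uM = rep(conc, each = n_rep),
    replicate = rep(seq_len(n_rep), length(conc)))
  new_experiment(counts, design, chemical_id = "test")
}

test_that("log2 CPM normalization follows the stated formula", {
  set.seed(31)
  n_s <- 33
  counts <- matrix(rpois(50 * n_s, 200), 50,
                   dimnames = list(sprintf("p%02d", 1:50),
                                   sprintf("s%02d_r%d", rep(1:11, each = 3),
                                           rep(1:3, 11))))
  ex <- make_experiment_from_counts(counts)
  exprs <- normalize_log2cpm(ex)
  # identical samples get identical size factors and outputs
  counts2 <- counts
  counts2[, 2] <- counts2[, 1]
  ex2 <- make_experiment_from_counts(counts2)
  exprs2 <- normalize_log2cpm(ex2)
  expect_equal(unname(exprs2$size_factors[1]),
               unname(exprs2$size_factors[2]))
  expect_equal(exprs2$log2cpm[, 1], exprs2$log2cpm[, 2],
               ignore_attr = TRUE)
  # arithmetic of the formula: count whose normalized CPM is x maps to
  # log2(x + 1); verify against a direct independent computation
  sf <- exprs$size_factors
  norm <- sweep(counts, 2, sf, "/")
  manual <- log2(sweep(norm, 2, colSums(norm), "/") * 1e6 + 1)
  expect_equal(exprs$log2cpm, manual)
  # scale invariance: doubling every count in one sample leaves its
  # log2 CPM column unchanged (size factor absorbs the scale)
  counts3 <- counts
  counts3[, 5] <- counts3[, 5] * 2
  exprs3 <- normalize_log2cpm(make_experiment_from_counts(counts3))
  expect_equal(exprs3$log2cpm[, 5], exprs$log2cpm[, 5], tolerance = 1e-10)
  # zero-total sample is a data error
  counts4 <- counts
  counts4[, 3] <- 0
  expect_error(normalize_log2cpm(make_experiment_from_counts(counts4)),
               class = "txpod_data_error")
})

test_that("size factors match the DESeq2 median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(32)
  counts <- matrix(rnbinom(100 * 33, mu = 150, size = 10), 100,
                   dimnames = list(sprintf("p%03d", 1:100),
                                   sprintf("s%02d_r%d", rep(1:11, each = 3),
                                           rep(1:3, 11))))
  ex <- make_experiment_from_counts(counts)
  exprs <- normalize_log2cpm(ex)
  oracle <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(exprs$size_factors), unname(oracle), tolerance = 1e-8)
})

test_that("PAVA is monotone, mean-preserving, and matches the R oracle", {
  set.seed(33)
  for (i in 1:25) {
    g <- sample(3:12, 1)
    y <- rnorm(g)
    w <- sample(1:5, g, replace = TRUE)
    iso <- txpod:::cpp_pava(y, w)
    expect_true(!is.unsorted(iso))
    expect_equal(sum(iso * w), sum(y * w), tolerance = 1e-10)
    expect_equal(iso, oracle_pava(y, w), tolerance = 1e-10)
  }
})

test_that("the Williams statistic matches an independent implementation", {
  set.seed(34)
  design <- data.frame(concentration_uM = rep(c(0, 1, 3, 10, 30, 100),
                                              each = 3))
  groups <- match(design$concentration_uM,
                  sort(unique(design$concentration_uM)))
  for (i in 1:20) {
    v <- rnorm(nrow(design)) + 0.2 * groups * rbinom(1, 1, 0.5)
    got <- williams_trend_p(v, design, B = 99, seed = i)
    expect_equal(got$t_stat, oracle_williams_stat(v, groups),
                 tolerance = 1e-10)
  }
})

test_that("degenerate probes behave as specified", {
  design <- data.frame(concentration_uM = rep(c(0, 1, 3, 10, 30, 100),
                                              each = 3))
  flat <- williams_trend_p(rep(5, 18), design, B = 99, seed = 1)
  expect_equal(flat$t_stat, 0)
  expect_equal(flat$p, 1)
  # zero pooled variance with unequal means: floor with warning
  step <- rep(c(0, 0, 0, 1, 1, 1), each = 3)
  expect_warning(res <- williams_trend_p(step, design, B = 99, seed = 1),
                 "zero pooled")
  expect_equal(res$p, 2 / (99 + 1))
})

test_that("a strong monotone trend reaches the permutation floor", {
  design <- data.frame(concentration_uM = rep(c(0, 1, 3, 10, 30, 100),
                                              each = 3))
  set.seed(35)
  v <- rep(1:6, each = 3) * 2 + rnorm(18, 0, 0.05)
  res <- williams_trend_p(v, design, B = 999, seed = 8)
  # two-directional doubling: reported floor is 2/(B+1)
  expect_equal(res$p, 2 / (999 + 1))
  expect_equal(res$direction, "up")
})

test_that("permutation p-values are calibrated under a Gaussian null", {
  set.seed(36)
  design <- data.frame(
    sample_id = sprintf("s%02d", 1:33),
    concentration_uM = rep(c(0, 10^seq(-3, 2, length.out = 10)), each = 3),
    replicate = rep(1:3, 11))
  vals <- matrix(rnorm(400 * 33), 400,
                 dimnames = list(sprintf("p%03d", 1:400), design$sample_id))
  ex <- structure(list(log2cpm = vals, size_factors = rep(1, 33),
                       design = design, chemical_id = "null"),
                  class = "txpod_exprs")
  pf <- prefilter_probes(ex, B = 299, seed = 12, fc_threshold = 0)
  rate <- mean(pf$table$p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("fold-change gate follows the stated arithmetic and is inclusive", {
  # three probes: dose shifts of 0.7, 0.5 and exactly log2(1.5) from control
  gm <- rbind(c(5, rep(5, 9), 5.7),
              c(5, rep(5, 9), 5.5),
              c(5, rep(5, 9), 5 + log2(1.5)))
  ex <- make_exprs(gm, sd = 0)
  suppressWarnings(pf <- prefilter_probes(ex, B = 99, seed = 2))
  expect_equal(pf$table$max_fc, c(2^0.7, 2^0.5, 1.5), tolerance = 1e-10)
  expect_true(pf$table$max_fc[1] >= 1.5)
  expect_false(pf$table$max_fc[2] >= 1.5)
  # exact threshold is inclusive: given a significant p the probe passes
  expect_true(pf$table$pass[3] == (pf$table$p[3] < 0.05))
})

test_that("the pass-set shrinks as thresholds tighten", {
  set.seed(37)
  sim <- simulate_experiment(sim_config(n_probes = 150,
                                        fraction_responsive = 0.4),
                             seed = 14, "shrink-chem")
  ex <- normalize_log2cpm(sim$experiment)
  loose <- prefilter_probes(ex, p_threshold = 0.1, fc_threshold = 1.2,
                            B = 199, seed = 3)
  tight_p <- prefilter_probes(ex, p_threshold = 0.01, fc_threshold = 1.2,
                              B = 199, seed = 3)
  tight_fc <- prefilter_probes(ex, p_threshold = 0.1, fc_threshold = 2,
                               B = 199, seed = 3)
  expect_true(all(tight_p$pass %in% loose$pass))
  expect_true(all(tight_fc$pass %in% loose$pass))
})
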