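conc6 <- rep(c(0, 0.5, 1, 2, 5, 10), each = 3)

test_that("exact-model recovery: linear data gives back slope and intercept", {
  y <- 2 + 0.3 * conc6
  fits <- fit_family(conc6, y + rnorm(length(y), 0, 1e-6))
  expect_equal(unname(fits$linear$params["b1"]), 0.3, tolerance = 1e-4)
  expect_equal(unname(fits$linear$params["b0"]), 2, tolerance = 1e-4)
  expect_lt(abs(fits$poly2$params["b2"]), 1e-3)
})

test_that("power exponent never drops below one", {
  # concave-up early rise (sqrt-like) tempts delta < 1
  set.seed(41)
  y <- 2 + sqrt(conc6) + rnorm(length(conc6), 0, 0.05)
  fits <- fit_family(conc6, y)
  expect_gte(unname(fits$power$params["d"]), 1)
})

test_that("exp4 data is fit at least as well by exp4 as by linear", {
  set.seed(42)
  mu <- 8 * (3 - 2 * exp(-0.8 * conc6))
  y <- mu + rnorm(length(mu), 0, 0.05)
  fits <- fit_family(conc6, y)
  expect_gte(fits$exp4$loglik, fits$linear$loglik)
})

test_that("model selection applies the nested test, AIC, and tie-breaks", {
  # nested chi-square size: on linear truth Poly2 is rejected ~95% of the time
  set.seed(43)
  kept_poly <- vapply(1:120, function(i) {
    y <- 1 + 0.5 * conc6 + rnorm(length(conc6), 0, 0.3)
    fits <- list(linear = txpod:::fit_linear(conc6, y),
                 poly2 = txpod:::fit_poly2(conc6, y))
    select_model(fits)$family == "poly2"
  }, logical(1))
  expect_lt(mean(kept_poly), 0.10)

  # identical AIC: fewer parameters win
  f3 <- list(family = "exp4", aic = 10, k_mean = 3L, converged = TRUE)
  f4 <- list(family = "exp5", aic = 10, k_mean = 4L, converged = TRUE)
  expect_equal(select_model(list(exp5 = f4, exp4 = f3))$family, "exp4")
  # singleton converged fit is selected
  only <- list(exp2 = list(family = "exp2", aic = 5, k_mean = 2L,
                           converged = TRUE))
  expect_equal(select_model(only)$family, "exp2")
  # nothing converged
  none <- list(exp2 = list(family = "exp2", aic = 5, k_mean = 2L,
                           converged = FALSE))
  expect_null(select_model(none))
})

test_that("deviance of Poly2 vs Linear is never negative and AIC never picks a non-converged fit", {
  set.seed(44)
  for (i in 1:10) {
    y <- rnorm(length(conc6), 5, 0.5)
    fits <- fit_family(conc6, y)
    expect_gte(fits$poly2$loglik, fits$linear$loglik - 1e-8)
    best <- select_model(fits)
    expect_true(best$converged)
  }
})

test_that("BMC inversion matches closed forms for Linear and Exp2", {
  # linear: mu = b0 + 2c, sigma = 1 -> bmc = 0.5
  lin <- list(family = "linear", params = c(b0 = 1, b1 = 2), s = NULL,
              sigma = 1, converged = TRUE)
  got <- bmc_from_fit(lin, bmr_k = 1, c_top = 10)
  expect_equal(got$bmc, 0.5, tolerance = 1e-5)

  # oracle equivalence on random draws
  set.seed(45)
  for (i in 1:50) {
    b1 <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    sig <- runif(1, 0.05, 2)
    lin$params["b1"] <- b1; lin$sigma <- sig
    expected <- oracle_bmc_linear(b1, sig)
    if (expected > 10) next
    expect_equal(bmc_from_fit(lin, 1, 10)$bmc, expected,
                 tolerance = 1e-5)
    a <- runif(1, 2, 12); b <- runif(1, 0.05, 0.5); s <- sample(c(-1, 1), 1)
    sig2 <- runif(1, 0.05, min(1, a / 2))
    e2 <- list(family = "exp2", params = c(a = a, b = b), s = s,
               sigma = sig2, converged = TRUE)
    expected2 <- oracle_bmc_exp2(a, b, s, sig2)
    if (expected2 > 10) next
    expect_equal(bmc_from_fit(e2, 1, 10)$bmc, expected2, tolerance = 1e-5)
  }
})

test_that("flat fits and below-range crossings are handled", {
  flat <- list(family = "linear", params = c(b0 = 1, b1 = 0), s = NULL,
               sigma = 1, converged = TRUE)
  got <- bmc_from_fit(flat, 1, 10)
  expect_true(is.na(got$bmc))
  expect_equal(got$reason, "no BMC <= top")
  # steep slope: bmc below the lowest tested dose is flagged, not dropped
  steep <- list(family = "linear", params = c(b0 = 1, b1 = 100), s = NULL,
                sigma = 0.5, converged = TRUE)
  got2 <- bmc_from_fit(steep, 1, 10, c_min = 0.1)
  expect_equal(got2$bmc, 0.005, tolerance = 1e-5)
  expect_true(got2$extrapolated)
})

test_that("profile bounds bracket the BMC and tighten with replication", {
  set.seed(46)
  widths <- vapply(c(3, 12), function(n_rep) {
    conc <- rep(c(0, 0.5, 1, 2, 5, 10), each = n_rep)
    y <- 2 + 0.4 * conc + rnorm(length(conc), 0, 0.3)
    fits <- fit_family(conc, y)
    best <- select_model(fits)
    inv <- bmc_from_fit(best, 1, 10)
    pb <- profile_bounds(best, inv$bmc, conf = 0.95, bmr_k = 1, c_top = 10)
    expect_lte(pb$bmcl, inv$bmc)
    expect_gte(pb$bmcu, inv$bmc)
    log10(pb$bmcu / pb$bmcl)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("post-filters drop by fit p, CI ratio, and top concentration", {
  rec <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    fit_p = c(0.05, 0.5, 0.5, 0.5),
    bmc = c(1, 1, 100, 101),
    bmcl = c(0.5, 0.1, 50, 50),
    bmcu = c(2, 4.6, 80, 120),
    drop_reason = NA_character_,
    stringsAsFactors = FALSE)
  kept <- postfilter_records(rec, c_top = 100)
  expect_setequal(kept$probe_id, "c")  # bmc == c_top exactly is retained
  dropped <- attr(kept, "dropped")
  expect_equal(dropped$drop_reason[dropped$probe_id == "a"], "fit p < 0.1")
  expect_equal(dropped$drop_reason[dropped$probe_id == "b"],
               "BMCU/BMCL > 40")
  expect_equal(dropped$drop_reason[dropped$probe_id == "d"],
               "BMC > top concentration")
})

test_that("probe-to-gene collapse takes the most sensitive probe", {
  rec <- data.frame(probe_id = c("p1", "p2", "p3"),
                    bmc = c(2.0, 0.5, 7), bmcl = c(1, 0.2, 5),
                    bmcu = c(4, 1, 9), stringsAsFactors = FALSE)
  map <- c(p1 = "g1", p2 = "g1", p3 = "g2")
  genes <- collapse_to_genes(rec, map)
  expect_equal(genes$bmc[genes$gene_id == "g1"], 0.5)
  expect_equal(genes$bmcl[genes$gene_id == "g1"], 0.2)
  expect_equal(nrow(genes), 2)
  # unmapped probes excluded with a warning
  expect_warning(g2 <- collapse_to_genes(rec, map[-3]), "not in the probe map")
  expect_equal(nrow(g2), 1)
})

test_that("fit_bmc produces coherent records on a small responsive panel", {
  set.seed(47)
  sim <- simulate_experiment(
    sim_config(n_probes = 40, fraction_responsive = 0.5,
               e_range = c(2, 2), dispersion = 0.02),
    seed = 3, "panel-chem")
  ex <- normalize_log2cpm(sim$experiment)
  pf <- prefilter_probes(ex, B = 199, seed = 5)
  rec <- fit_bmc(ex, pf$pass)
  ret <- postfilter_records(rec, 100)
  expect_true(all(!is.na(ret$bmc)))
  expect_true(all(ret$bmcl <= ret$bmc + 1e-9))
  expect_true(all(ret$bmcu >= ret$bmc - 1e-9))
  expect_true(all(ret$bmc <= 100))
  expect_true(all(ret$fit_p >= 0.1))
})
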