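---
title: "Deriving transcriptomic points of departure with txpod: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving transcriptomic points of departure with txpod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txpod)
```

## The problem

High-throughput transcriptomics measures how a cell model's gene expression
responds across a concentration series of a test chemical. A transcriptomic
point of departure (tPOD) summarizes where concerted expression change
begins — a concentration, in µM, intended to be protective of downstream
apical effects. `txpod` implements a uniform workflow from a probe-by-sample
count matrix to a tPOD, converts the tPOD to an administered equivalent dose
(AED, mg/kg-bw/day) by steady-state reverse dosimetry, and compares that AED
to an apical point of departure from animal studies via a log10-ratio
outlier statistic.

Because the workflow spans several modeling stages, each with conventions
that differ between software packages, this vignette records exactly what
is computed, which parameters matter, and which choices were genuinely open.

## Normalization

Counts are normalized in two steps. Size factors come from the
median-of-ratios method (each sample's median ratio to the per-probe
geometric-mean reference, over probes with all-positive counts) — the same
estimator DESeq2 uses, and the test suite checks agreement with DESeq2 on
random matrices. Normalized counts are then expressed per million within
each sample and shifted by one before the log:

$$y_{ps} = \log_2\!\left(\frac{c_{ps}/f_s}{\sum_p c_{ps}/f_s} \times 10^6 + 1\right).$$

Note the second step (counts per million within sample) re-introduces a
compositional coupling that the size factors had removed: when strongly
responsive, highly expressed probes shift a sample's total, every other
probe in that sample inherits a small opposite shift. On simulated data
this measurably inflates the trend-test rejection rate of truly null probes
at some seeds (7–10% instead of the nominal 5%) while the permutation test
itself is exactly calibrated on exchangeable data. We keep the formula as
stated because it mirrors the upstream convention (DESeq2 size factors, then
log2 CPM); users comparing chemicals with massive transcriptional responses
should be aware of the effect.

## Prefilter: trend test and fold change

A probe is carried into dose-response modeling only if it shows a
concentration-dependent trend and a material effect size:

* **Williams-type trend test.** Group means (ordered control, then
  increasing concentration) are amalgamated with weighted
  pool-adjacent-violators to enforce monotonicity; the statistic is the
  amalgamated top-group mean minus the raw control mean, standardized by
  the pooled within-group variance. Because published critical-value
  tables cover only balanced designs and specific group counts, p-values
  come from permuting sample labels (`B = 999` by default, seeded). Both
  directions are tested and the smaller p-value is doubled — a Bonferroni
  correction over direction — so the attainable floor is `2/(B+1)`.
* **Fold change.** On log2 CPM group means, the max absolute difference
  from control converts to a fold change `2^|Δ|`; probes need at least 1.5
  (inclusive) in some concentration.

The permutation stream is shared across probes (standard practice; marginal
p-values are unaffected, joint fluctuations are correlated — visible as
seed-to-seed variation in genome-wide rejection counts).

## Dose-response models and the benchmark concentration

Seven families are fit per probe by constant-variance normal maximum
likelihood: Linear, Poly2, Power (exponent restricted to [1, 18]), and the
four exponential forms

$$\mathrm{Exp2}: a e^{sbc},\quad \mathrm{Exp3}: a e^{s(bc)^d},\quad
\mathrm{Exp4}: a(k - (k-1)e^{-bc}),\quad \mathrm{Exp5}: a(k - (k-1)e^{-(bc)^d}),$$

with $a > 0$, $b > 0$, $d \ge 1$, and $k > 1$ (increasing) or $0 < k < 1$
(decreasing). These forms are a reconstruction of the EPA continuous-model
family used by BMD software; the exact parameterizations are visible in
`predict_mu()`. Fitting profiles the linear parameters out exactly (OLS)
and searches the nonlinear parameters on deterministic log-spaced grids
with `nlminb` refinement from the best grid points, capped at 250
iterations — a deterministic multi-start scheme.

Model selection: Poly2 replaces Linear only if the nested chi-square test
(deviance on 1 df) rejects at 0.05; the survivor competes with Power and
Exp2–5 on lowest AIC (`AIC = 2(k_{mean}+1) - 2\ell`, counting σ), ties to
fewer parameters, then family order.

The benchmark response is one fitted residual standard deviation (BMR =
1 SD). The BMC is the first concentration where $|\mu(c) - \mu(0)|$ reaches
$\hat\sigma$, found by sign-bracketing on a log grid plus bisection
(relative tolerance 1e-6), searched in $(0, c_{top}]$; crossings below the
lowest tested dose are flagged as extrapolated. Whether "1 SD" means the
modeled residual SD or the control-group SD is a genuinely open convention;
the modeled $\hat\sigma$ is the default here because it is the quantity the
likelihood estimates jointly with the curve.

Confidence bounds are profile-likelihood: the BMC is made an explicit
parameter by solving one mean parameter from the constraint
$|\mu(b)-\mu(0)| = k\hat\sigma$ (this couples the mean parameters to σ,
which is profiled numerically), and each bound sits where the profile
deviance reaches $\chi^2_1(0.90) = 2.706$ — one-sided 95% per bound, the
convention BMD software uses when "a 0.95 confidence interval" is stated.
The search is bounded to $[c_{top}\cdot10^{-6},\ c_{top}\cdot10^{3}]$.

Post-filters remove records with goodness-of-fit p < 0.1 (deviance against
the saturated group-means model, df = groups − mean parameters), BMCU/BMCL
> 40, or BMC above the top tested concentration. Probes collapse to genes
by keeping the probe with the lowest BMC.

## The five tPODs

Given the gene-level BMC list:

* **p5** — the value at 1-based rank `max(1, floor(0.05 n))`. The floor
  rule (not an interpolated percentile) is the primary variant because it
  is the deterministic formula given for this metric; with n < 20 it
  degrades to the minimum BMC, which is why chemicals with few modeled
  genes get near-minimum tPODs.
* **mode1** — Gaussian KDE of log10(BMC) (Silverman bandwidth, 512-point
  grid spanning the data ± one bandwidth); first grid point where the
  finite-difference first derivative crosses + → − with negative second
  derivative. Monotone densities fall back to the boundary maximum,
  flagged. Needs ≥ 5 genes.
* **rank25** — the 25th-lowest gene BMC; inactive below 25 genes.
* **lcrd** (modified) — sort BMCs; chain into consistent response groups
  wherever the consecutive ratio is ≤ 1.66; take the minimum of the
  *largest* group (ties: the group with the smaller minimum). This
  discards small isolated clusters of implausibly low BMCs. The 1.66
  threshold is retained even though a quarter-log spacing would be
  $10^{0.25} \approx 1.78$; the two glosses conflict and 1.66 is the
  operative number.
* **geneset** — over one or more collections (GO-BP / Reactome / KEGG
  roles), a set qualifies with ≥ 3 member genes having BMCs covering ≥ 5%
  of its annotated size; its statistic is the median member BMC, and the
  tPOD is the minimum over qualifying sets. The winning set's function is
  recorded but deliberately not interpreted.

The per-chemical spread, log10(max/min) over defined tPODs, quantifies
cross-method concordance.

## Reverse dosimetry

The steady-state model is a reconstruction of a three-compartment
steady-state toxicokinetic model: well-stirred hepatic clearance
$CL_h = Q_h f_{ub} CL_{int}/(Q_h + f_{ub} CL_{int})$ (intrinsic clearance
scaled from µL/min/10⁶ hepatocytes by hepatocellularity 110 × 10⁶ cells/g,
liver mass 25.7 g/kg, 1440 min/day), renal clearance $GFR \cdot f_{ub}$
(GFR 2.2 L/day/kg), full gut absorption unless a fraction is supplied, and
blood:plasma ratio 1. At a unit oral dose rate,
$C_{ss} = f_{abs}/(GFR \cdot f_{ub} + CL_h)$ in mg/L, converted to µM
through the molecular weight. All physiological constants are arguments
with documented human defaults.

Population variability is a transparent stand-in for a full population
simulator: independent lognormal multipliers (median 1, CV 0.3) on
$f_{ub}$ (truncated at 1), $CL_{int}$, GFR and $Q_h$; the 95th percentile
of the resulting Css distribution is used. Applying the quantile to Css
(not to the dose distribution) yields the lower, conservative AED; that
interpretation is a choice, noted here, and `cv = 0` recovers the
deterministic model exactly.

$$AED = tPOD\ (\mu M) \times \frac{1\ \mathrm{mg/kg/day}}{C_{ss}\ (\mu M)}$$

## Comparison and outliers

Per chemical and per track (the BMC-distribution track pools p5, mode1,
rank25, lcrd across a chemical's experiments; the gene-set track pools
gene-set AEDs), the lowest AED is selected with its provenance, then

$$\mathrm{Log_{10}Ratio} = \log_{10}(POD_{traditional}) - \log_{10}(AED_{NAM}),$$

with ratio < 0 flagging the chemical as an outlier (the NAM estimate is
less conservative than the animal POD). Chemicals missing either an AED or
an apical POD appear in a coverage table rather than vanishing — attrition
is part of the result.

## The synthetic world

Real TempO-Seq datasets in this problem area are available only on request,
so validation runs on a generator with known ground truth. Per probe,
counts are negative binomial (dispersion φ, default 0.05) around
$\mu_p \cdot \ell_s \cdot 2^{sE c^h/(AC_{50}^h + c^h)}$: lognormal baseline
means (median 100, sdlog 1.2 — a skewed targeted panel), lognormal
library-size factors (sdlog 0.15), and for the responsive fraction
(default 10%) a Hill-shaped log2 shift with AC50 log-uniform in
[0.005, 50] µM, amplitude E uniform in [1, 3], Hill coefficient uniform in
[1, 3], sign fair-coin. The design mirrors the source studies: ten
log-spaced concentrations over [0.0005, 100] µM plus solvent controls,
three replicates. The ground-truth BMC solves the noiseless Hill curve at a
benchmark shift equal to each probe's approximate within-group SD
($\sqrt{\log(1+1/\mu_p+\varphi)}/\log 2$), fixed by design so recovery
statements have a stable target rather than chasing the per-fit
$\hat\sigma$.

What the generator does **not** emulate: probe cross-hybridization, batch
effects, sample swaps, heteroscedastic dispersion trends, and correlated
co-regulation among genes. A green recovery test therefore establishes
that the modeling chain is correct and well-calibrated on clean
concentration-response structure — not that real-data artifacts are
handled.

Reference tables for end-to-end tests are constructed, not measured:
toxicokinetic parameters are drawn from screening-level ranges (MW
100–500, $f_{ub}$ log-uniform 0.05–1, $CL_{int}$ log-uniform 0.5–50), and
each chemical's apical POD is placed a designed number of decades
(`margin`) above or below its designed AED, so the expected sign of every
log10 ratio is known by construction.

## Known limitations and honest reds

* **BMC recovery vs a 2-fold tolerance.** On Hill-generated truth at this
  design (3 replicates, BMR = 1 SD), roughly a quarter of retained
  responsive probes land outside 2-fold of truth even at low dispersion.
  Two causes, both structural: the model family (which excludes Hill by
  scope) rises from c = 0 with nonzero or linear slope while a Hill curve
  with h > 1 is flat at the origin, so fitted curves cross the benchmark
  slightly early (a ~0.9× geometric bias, concentrated at h > 2); and the
  sampling noise of $\hat\sigma$ and the fitted curve puts the typical BMC
  error near 2.3-fold. In the misses, the fitted curve's RSS is *better*
  than the true Hill shape's RSS over 90% of the time — the estimates are
  faithful to the data, the tolerance is simply tighter than the
  estimator's noise at this design. The corresponding acceptance assertion
  is left failing rather than loosened.
* **Trend-test inflation under composition shifts**, described above: a
  property of CPM-after-size-factors, not of the permutation machinery.
* The LCRD threshold, the 5% fold-change-scale convention (group means of
  log2 CPM), one- vs two-sided trend testing (two-sided chosen, exposed in
  config), and the quantile-on-Css interpretation are conventions chosen
  once and surfaced as arguments rather than buried.

## Tunable parameters at a glance

| parameter | default | where | meaning |
|---|---|---|---|
| `p_threshold` | 0.05 | prefilter | trend-test gate (strict <) |
| `fc_threshold` | 1.5 | prefilter | max fold-change gate (inclusive) |
| `B` | 999 | prefilter | permutations; p floor 2/(B+1) |
| `bmr_k` | 1 | bmc | benchmark response in SDs |
| `conf` | 0.95 | bmc | per-bound one-sided coverage via χ²₁(0.90) |
| `alpha_nested` | 0.05 | bmc | Linear vs Poly2 nested test |
| fit p / CI ratio / top | 0.1, 40, c_top | postfilter | record removal rules |
| `lcrd_ratio` | 1.66 | tpod | consecutive-ratio group boundary |
| `n_rank` | 25 | tpod | ranked-gene threshold |
| `min_genes`, `min_frac` | 3, 0.05 | tpod | gene-set qualification |
| `GFR`, `Qh` | 2.2, 24 L/day/kg | ivive | human physiology |
| `cv`, `n_draws` | 0.3, 1000 | ivive | population variability |

## A worked example

```{r example, eval = FALSE}
sim <- simulate_experiment(sim_config(n_probes = 400,
                                      fraction_responsive = 0.25),
                           seed = 1, chemical_id = "demo-1")
res <- run_experiment(sim$experiment, sim$probe_map, seed = 1)
res$tpods$results$lcrd
tk <- data.frame(casrn = "demo-1", mw = 250, fub = 0.4, clint = 8, fabs = 1)
css <- css_quantile_mc(tk, seed = 1)
aed_from_tpod(res$tpods$results$lcrd$value, css$css_q95)
```

The README shows this flow with the numbers it actually printed.
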