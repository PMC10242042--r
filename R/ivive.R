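# Reverse dosimetry: a reconstructed three-compartment steady-state model
# (well-stirred liver plus renal clearance by glomerular filtration of the
# unbound fraction, full gut absorption by default) gives the steady-state
# plasma concentration Css at a unit oral dose rate; the administered
# equivalent dose is then AED = tPOD / Css. Population variability enters
# through independent lognormal multipliers on the physiological and
# chemical parameters, and the conservative 95th-quantile Css is used.

#' Default adult-human physiology for the steady-state model
#'
#' @param Qh hepatic blood flow, L/day/kg body weight (default 24:
#'   ~90 L/h scaled to 70 kg and 24 h).
#' @param GFR glomerular filtration rate, L/day/kg BW (default 2.2).
#' @param liver_mass_per_kg grams of liver per kg BW (default 25.7:
#'   1.8 kg liver / 70 kg).
#' @param hepatocellularity 10^6 hepatocytes per gram of liver (default 110).
#' @return list of class `txpod_physiology`.
#' @export
physiology_defaults <- function(Qh = 24, GFR = 2.2, liver_mass_per_kg = 25.7,
                                hepatocellularity = 110) {
  phys <- list(Qh = Qh, GFR = GFR, liver_mass_per_kg = liver_mass_per_kg,
               hepatocellularity = hepatocellularity)
  if (any(unlist(phys) <= 0)) config_error("physiology values must be > 0")
  class(phys) <- "txpod_physiology"
  phys
}

css_from_params <- function(mw, fub, clint, fabs, Qh, GFR, liver_mass_per_kg,
                            hepatocellularity) {
  # scale intrinsic clearance from uL/min/10^6 cells to L/day/kg BW
  clint_L <- clint * hepatocellularity * liver_mass_per_kg * 1440 * 1e-6
  clh <- Qh * fub * clint_L / (Qh + fub * clint_L)
  clh[!is.finite(clh)] <- 0  # clint = 0 and fub = 0 both give no hepatic clearance
  total <- GFR * fub + clh
  css_mg_L <- fabs / total  # unit dose rate: 1 mg/kg/day
  css_mg_L / mw * 1e3       # -> µM (mg/L / (g/mol) * 1000)
}

#' Steady-state plasma concentration at a unit oral dose
#'
#' Deterministic Css (µM) for a continuous oral dose rate of
#' 1 mg/kg-bw/day.
#'
#' @param tk_row single row of a TK table (`mw`, `fub`, `clint`, optional
#'   `fabs`).
#' @param physiology a [physiology_defaults()] object.
#' @return Css in µM.
#' @export
css_unit_dose <- function(tk_row, physiology = physiology_defaults()) {
  fub <- tk_row$fub; clint <- tk_row$clint
  fabs <- tk_row$fabs %||% 1
  if (is.na(fabs)) fabs <- 1
  if (fub <= 0) {
    txpod_error("txpod_css_error",
                "total clearance is zero (fraction unbound = 0): Css undefined")
  }
  css <- css_from_params(tk_row$mw, fub, clint, fabs, physiology$Qh,
                         physiology$GFR, physiology$liver_mass_per_kg,
                         physiology$hepatocellularity)
  if (!is.finite(css) || css <= 0) {
    txpod_error("txpod_css_error", "Css is undefined for this chemical")
  }
  css
}

#' Monte Carlo 95th-quantile steady-state concentration
#'
#' Per draw, the fraction unbound (truncated at 1), intrinsic clearance,
#' GFR and hepatic blood flow are each multiplied by an independent
#' lognormal factor with median 1 and coefficient of variation `cv`; the
#' reported `css_q95` is the empirical 95th percentile of the per-draw Css
#' values — the right tail of the population distribution, which gives the
#' lower, more conservative AED.
#'
#' @param tk_row single TK table row.
#' @param physiology a [physiology_defaults()] object.
#' @param n_draws Monte Carlo draws (>= 100; default 1000).
#' @param cv coefficient of variation of the lognormal multipliers
#'   (default 0.3); `cv = 0` collapses to the deterministic Css.
#' @param seed integer seed (the result is deterministic given the seed).
#' @param return_draws also return the per-draw Css vector (for
#'   diagnostics).
#' @return list of class `txpod_tk_result`: `chemical_id`, `css_unit`,
#'   `css_q95`, `n_draws`, `seed` (and `draws` when requested).
#' @export
css_quantile_mc <- function(tk_row, physiology = physiology_defaults(),
                            n_draws = 1000L, cv = 0.3, seed = 1L,
                            return_draws = FALSE) {
  if (n_draws < 100L) config_error("n_draws must be >= 100")
  css0 <- css_unit_dose(tk_row, physiology)
  if (cv == 0) {
    return(structure(list(chemical_id = tk_row$casrn %||% NA_character_,
                          css_unit = css0, css_q95 = css0,
                          n_draws = as.integer(n_draws), seed = seed),
                     class = "txpod_tk_result"))
  }
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(seed)
  mult <- matrix(rlnorm(4 * n_draws, 0, sdlog), n_draws, 4)
  fabs <- tk_row$fabs %||% 1
  if (is.na(fabs)) fabs <- 1
  css <- css_from_params(tk_row$mw,
                         pmin(tk_row$fub * mult[, 1], 1),
                         tk_row$clint * mult[, 2],
                         fabs,
                         physiology$Qh * mult[, 4],
                         physiology$GFR * mult[, 3],
                         physiology$liver_mass_per_kg,
                         physiology$hepatocellularity)
  ok <- is.finite(css) & css > 0
  if (mean(ok) < 0.5) {
    txpod_error("txpod_css_error",
                "more than half of the Monte Carlo draws give an undefined Css")
  }
  out <- list(chemical_id = tk_row$casrn %||% NA_character_,
              css_unit = css0,
              css_q95 = unname(quantile(css[ok], 0.95, type = 7)),
              n_draws = as.integer(n_draws), seed = seed)
  if (return_draws) out$draws <- css[ok]
  structure(out, class = "txpod_tk_result")
}

#' Administered equivalent dose from a tPOD
#'
#' AED (mg/kg-bw/day) = tPOD (µM) × 1 (mg/kg-bw/day) / Css (µM): the
#' external dose whose steady-state plasma concentration equals the in
#' vitro bioactive concentration.
#'
#' @param tpod_uM tPOD in µM (> 0).
#' @param css_uM steady-state concentration at unit dose, in µM (> 0);
#'   typically the conservative `css_q95`.
#' @return AED in mg/kg-bw/day.
#' @export
aed_from_tpod <- function(tpod_uM, css_uM) {
  if (any(!is.finite(tpod_uM) | tpod_uM <= 0)) {
    data_error("tPOD must be positive to convert to an AED")
  }
  if (any(!is.finite(css_uM) | css_uM <= 0)) {
    txpod_error("txpod_css_error", "Css must be positive to convert to an AED")
  }
  tpod_uM / css_uM
}
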