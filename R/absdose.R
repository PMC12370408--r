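# Absolute-dose correction chain.  A simulated per-particle dose D_dpp is
# converted to absolute dose (cGy/MU) by the product
#   D_abs = D_dpp * R_ch * F_backscatter * F_cal
# where R_ch rescales for the degradation-induced change in monitor-chamber
# response, F_backscatter corrects for field-size-dependent jaw backscatter
# into the chamber (1 at the 10 cm reference field, nominal-condition
# values used for degraded scenarios), and F_cal is the particle count per
# MU at calibration (10 cm field, SSD 100 cm, z_max, 1 cGy/MU).

#' Correction-factor set for the absolute-dose chain
#'
#' @param r_ch Named numeric vector of chamber response ratios per
#'   scenario; defaults to the tabulated reference ratios of the built-in
#'   scenarios.  Must satisfy `r_ch["NC"] == 1`.
#' @param f_backscatter Named numeric vector of backscatter corrections per
#'   field size (names are field sizes in cm); must be 1 at the 10 cm
#'   reference field.  The default table is a plausible monotone set
#'   normalized at 10 cm (backscatter corrections are inputs here: they
#'   require jaw-scatter transport to compute).
#' @param fcal Particles per MU at calibration.
#' @param fcal_rel_unc Relative uncertainty of `fcal`.
#' @param d_abs_cal Calibration dose, cGy/MU.
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(r_ch = rch_fixture_table(),
                               f_backscatter = default_backscatter(),
                               fcal = 9.3925e15, fcal_rel_unc = 0.0024,
                               d_abs_cal = 1) {
  if (any(r_ch <= 0) || any(f_backscatter <= 0) || fcal <= 0 || d_abs_cal <= 0)
    tdeg_error("factors", "all correction factors must be > 0")
  if (!isTRUE(all.equal(unname(r_ch["NC"]), 1)))
    tdeg_error("factors", "R_ch must be 1 under the nominal condition")
  if (!"10" %in% names(f_backscatter) ||
      !isTRUE(all.equal(unname(f_backscatter["10"]), 1)))
    tdeg_error("factors", "F_backscatter must be 1 at the 10 cm reference field")
  structure(list(r_ch = r_ch, f_backscatter = f_backscatter, fcal = fcal,
                 fcal_rel_unc = fcal_rel_unc, d_abs_cal = d_abs_cal),
            class = "correction_factors")
}

default_backscatter <- function() {
  c("3" = 0.9960, "6" = 0.9980, "10" = 1.0000, "15" = 1.0040,
    "20" = 1.0070, "30" = 1.0120)
}

lookup_rch <- function(factors, scenario) {
  nm <- if (is.character(scenario)) scenario else scenario$name
  if (!nm %in% names(factors$r_ch))
    tdeg_error("missing_factor", "no chamber response ratio for scenario '%s'", nm)
  unname(factors$r_ch[nm])
}

lookup_backscatter <- function(factors, field_size) {
  key <- format(field_size, trim = TRUE)
  if (!key %in% names(factors$f_backscatter))
    tdeg_error("missing_factor", "no backscatter factor for field size %s cm", key)
  unname(factors$f_backscatter[key])
}

#' Absolute dose from a simulated per-particle dose
#'
#' Applies the full correction chain `D_dpp * R_ch * F_backscatter *
#' F_cal` and propagates relative uncertainties in quadrature.  With all
#' factors at 1 and `d_dpp` equal to the calibration per-particle dose
#' `d_abs_cal / fcal`, the result is exactly the calibration dose.
#'
#' @param d_dpp Simulated dose per incident particle.
#' @param field_size Field size, cm (selects the backscatter factor).
#' @param scenario Scenario name or object (selects R_ch).
#' @param factors A [correction_factors()].
#' @param d_dpp_rel_unc Relative Monte Carlo uncertainty of `d_dpp`.
#' @return List with `value` (cGy/MU) and `rel_unc`.
#' @export
absolute_dose <- function(d_dpp, field_size, scenario = "NC",
                          factors = correction_factors(),
                          d_dpp_rel_unc = 0) {
  stopifnot(inherits(factors, "correction_factors"), d_dpp >= 0)
  rch <- lookup_rch(factors, scenario)
  fb <- lookup_backscatter(factors, field_size)
  value <- d_dpp * rch * fb * factors$fcal * factors$d_abs_cal
  list(value = value,
       rel_unc = sqrt(d_dpp_rel_unc^2 + factors$fcal_rel_unc^2))
}

#' Monitor-chamber dose amplification under degradation
#'
#' The fold increase of dose deposited in the monitor chamber relative to
#' baseline, `1 / R_ch`, rounded to two significant figures for reporting.
#'
#' @param scenario Scenario name or object.
#' @param factors A [correction_factors()].
#' @return Numeric fold increase.
#' @export
chamber_amplification <- function(scenario, factors = correction_factors()) {
  rch <- lookup_rch(factors, scenario)
  if (rch <= 0)
    tdeg_error("factors", "R_ch must be > 0")
  signif(1 / rch, 2)
}

#' Relative output factor
#'
#' `ROF = (D_dpp_f / D_dpp_10) * F_backscatter(f)`: the field-size output
#' relative to the 10 cm reference field, backscatter-corrected.  The
#' chamber ratio cancels because nominal-condition backscatter factors are
#' used for degraded scenarios as well.
#'
#' @param d_dpp_f Per-particle dose of the field of interest (at matched
#'   depth and conditions, conventionally 10 cm depth on the CAX).
#' @param d_dpp_10 Per-particle dose of the 10 cm reference field.
#' @param field_size Field size of `d_dpp_f`, cm.
#' @param factors A [correction_factors()].
#' @return Numeric ROF.
#' @export
rof <- function(d_dpp_f, d_dpp_10, field_size,
                factors = correction_factors()) {
  if (d_dpp_10 <= 0)
    tdeg_error("range", "reference-field dose must be > 0")
  d_dpp_f / d_dpp_10 * lookup_backscatter(factors, field_size)
}

#' Wedge factor
#'
#' Central-axis dose ratio wedge/open at z_max for a matched field and
#' scenario.  The monitor-chamber ratio is taken as 1: the wedge sits far
#' from the chamber and does not change its response.
#'
#' @param d_wedge,d_open Central-axis doses at z_max with and without the
#'   wedge.
#' @return Numeric WF.
#' @export
wedge_factor <- function(d_wedge, d_open) {
  if (d_open <= 0)
    tdeg_error("range", "open-field dose must be > 0")
  d_wedge / d_open
}

#' Percent deviation of an output from baseline
#'
#' `(test - baseline) / baseline * 100`; accepts plain numerics or the
#' `value` of [absolute_dose()] results.
#'
#' @param test,baseline Numeric outputs (or lists with a `value` field).
#' @return Signed percent deviation.
#' @export
output_deviation <- function(test, baseline) {
  tv <- if (is.list(test)) test$value else test
  bv <- if (is.list(baseline)) baseline$value else baseline
  if (bv == 0)
    tdeg_error("range", "baseline output is zero")
  (tv - bv) / bv * 100
}
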