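MOLAR_VOLUME_L <- 22.414   # L/mol at 0 degC, 1 atm ("standard litres")
CH4_MOLAR_MASS <- 16.04    # g/mol

#' Describe a chemostat growth condition
#'
#' Bundles the bioreactor settings needed to interpret off-gas series:
#' inlet gas composition, gas flow, culture volume, steady-state biomass
#' concentration and dilution rate (at steady state the specific growth
#' rate equals the dilution rate).
#'
#' @param label Condition token, e.g. `"Ca-optimal"`.
#' @param inlet_ch4_pct,inlet_o2_pct Inlet percentages (v/v), in
#'   `[0, 100]`.
#' @param gas_flow Gas flow in standard litres per hour (sL/h).
#' @param culture_volume Culture volume in litres.
#' @param biomass_conc Steady-state biomass in g DCW/L.
#' @param dilution_rate Dilution rate D in 1/h.
#' @return An object of class `"reeflux_condition"` (a list).
#' @export
condition_spec <- function(label, inlet_ch4_pct, inlet_o2_pct,
                           gas_flow = 1.0, culture_volume = 0.25,
                           biomass_conc, dilution_rate) {
  stopifnot(inlet_ch4_pct >= 0, inlet_ch4_pct <= 100,
            inlet_o2_pct >= 0, inlet_o2_pct <= 100,
            gas_flow > 0, culture_volume > 0, biomass_conc > 0,
            dilution_rate >= 0)
  structure(list(label = label, inlet_ch4_pct = inlet_ch4_pct,
                 inlet_o2_pct = inlet_o2_pct, gas_flow = gas_flow,
                 culture_volume = culture_volume,
                 biomass_conc = biomass_conc,
                 dilution_rate = dilution_rate),
            class = "reeflux_condition")
}

#' Reference chemostat conditions for the Ca/La switch study design
#'
#' The four steady-state conditions of a two-cation, two-gas-regime
#' continuous culture experiment: optimal supply (5% CH4 : 5% O2) and
#' methane-limited supply (2.5% CH4 : 10% O2) for calcium- and
#' lanthanum-supplemented cultures. Besides the [condition_spec()] each
#' entry carries the observed biomass yield (g DCW per g CH4) and, where
#' measured, the observed O2:CH4 consumption ratio — the quantities the
#' synthetic off-gas generator plants and [steady_state_summary()]
#' recovers.
#'
#' @return Named list; each element has `spec` ([condition_spec()]),
#'   `yield_biomass` and `ratio_o2_ch4` (`NA` where not measured).
#' @export
default_conditions <- function() {
  list(
    ca_optimal = list(
      spec = condition_spec("Ca-optimal", 5, 5, biomass_conc = 0.64,
                            dilution_rate = 0.05),
      yield_biomass = 1.2, ratio_o2_ch4 = 1.12),
    ca_limited = list(
      spec = condition_spec("Ca-limited", 2.5, 10, biomass_conc = 0.67,
                            dilution_rate = 0.05),
      yield_biomass = 0.98, ratio_o2_ch4 = NA_real_),
    la_optimal = list(
      spec = condition_spec("La-optimal", 5, 5, biomass_conc = 0.75,
                            dilution_rate = 0.07),
      yield_biomass = 0.64, ratio_o2_ch4 = 1.28),
    la_limited = list(
      spec = condition_spec("La-limited", 2.5, 10, biomass_conc = 0.45,
                            dilution_rate = 0.06),
      yield_biomass = 0.67, ratio_o2_ch4 = NA_real_))
}

#' Molar gas consumption from inlet/outlet percentages
#'
#' Converts the difference between inlet and outlet volume percentages at
#' a given gas flow into a molar consumption rate, using the ideal molar
#' volume of 22.414 L/mol for "standard litres".
#'
#' @param inlet_pct,outlet_pct Percent (v/v).
#' @param gas_flow Gas flow in sL/h.
#' @return Consumption in mmol/h (signed; negative values indicate net
#'   production and, for a consumed gas, are returned with a warning).
#' @examples
#' gas_molar_consumption(5, 3, 1)  # 0.892 mmol/h
#' @export
gas_molar_consumption <- function(inlet_pct, outlet_pct, gas_flow) {
  stopifnot(inlet_pct >= 0, inlet_pct <= 100, outlet_pct >= 0,
            gas_flow > 0)
  cons <- (inlet_pct - outlet_pct) / 100 * gas_flow / MOLAR_VOLUME_L * 1000
  if (cons < 0)
    warning("outlet exceeds inlet (net production); returning signed value")
  cons
}

#' Specific substrate consumption rate from growth rate and yield
#'
#' `q = 1000 * mu / (yield * molar_mass)` in mmol gDCW^-1 h^-1: the
#' specific consumption implied by a specific growth rate `mu` and a
#' biomass yield in g DCW per g substrate.
#'
#' @param mu Specific growth rate, 1/h.
#' @param yield_biomass Yield, g DCW per g substrate (> 0).
#' @param molar_mass Substrate molar mass, g/mol (default methane,
#'   16.04).
#' @return Specific consumption rate, mmol gDCW^-1 h^-1.
#' @examples
#' specific_consumption_rate(0.05, 1.2)   # ~2.60, Ca-optimal
#' specific_consumption_rate(0.06, 0.67)  # ~5.58, La methane-limited
#' @export
specific_consumption_rate <- function(mu, yield_biomass,
                                      molar_mass = CH4_MOLAR_MASS) {
  if (!is.numeric(yield_biomass) || any(yield_biomass <= 0))
    stop("yield_biomass must be > 0")
  stopifnot(all(mu >= 0), molar_mass > 0)
  1000 * mu / (yield_biomass * molar_mass)
}

#' Volumetric biomass productivity
#'
#' @param dilution_rate D, 1/h.
#' @param biomass_conc X, g DCW/L.
#' @param culture_volume V, L.
#' @return Productivity D*X*V in mg DCW/h.
#' @examples
#' biomass_productivity(0.05, 0.64, 1.0)  # 32 mg DCW/h
#' @export
biomass_productivity <- function(dilution_rate, biomass_conc,
                                 culture_volume) {
  stopifnot(dilution_rate >= 0, biomass_conc > 0, culture_volume > 0)
  dilution_rate * biomass_conc * culture_volume * 1000
}

#' Steady-state growth summary from an off-gas series
#'
#' Averages outlet gas percentages over a stated steady-state window,
#' converts them to molar consumption rates via
#' [gas_molar_consumption()], and derives the chemostat growth
#' parameters: `mu` (= dilution rate at steady state), biomass yield on
#' methane, specific CH4 and O2 consumption rates, the O2:CH4
#' consumption ratio and volumetric biomass productivity.
#'
#' @param spec A [condition_spec()].
#' @param offgas `data.frame` with columns `time_h`, `ch4_out_pct`,
#'   `o2_out_pct` (a `co2_out_pct` column is carried but not required).
#' @param window Length-2 numeric, inclusive time window (h) to average
#'   over; default the full series.
#' @return An object of class `"reeflux_growth_summary"`: list with `mu`,
#'   `yield_biomass`, `q_ch4`, `q_o2`, `ratio_o2_ch4`, `productivity`
#'   (mg DCW/h) and the window means.
#' @export
steady_state_summary <- function(spec, offgas, window = NULL) {
  stopifnot(inherits(spec, "reeflux_condition"), is.data.frame(offgas),
            all(c("time_h", "ch4_out_pct", "o2_out_pct") %in%
                  names(offgas)))
  if (is.null(window)) window <- range(offgas$time_h)
  keep <- offgas$time_h >= window[1] & offgas$time_h <= window[2]
  if (!any(keep)) stop("steady-state window contains no observations")
  ch4_out <- mean(offgas$ch4_out_pct[keep])
  o2_out <- mean(offgas$o2_out_pct[keep])

  ch4_mmol_h <- gas_molar_consumption(spec$inlet_ch4_pct, ch4_out,
                                      spec$gas_flow)
  o2_mmol_h <- gas_molar_consumption(spec$inlet_o2_pct, o2_out,
                                     spec$gas_flow)
  if (ch4_mmol_h <= 0)
    stop("non-positive CH4 consumption over the window")

  mu <- spec$dilution_rate
  biomass_g_h <- spec$biomass_conc * spec$dilution_rate *
    spec$culture_volume
  ch4_g_h <- ch4_mmol_h * CH4_MOLAR_MASS / 1000
  denom <- spec$biomass_conc * spec$culture_volume
  structure(
    list(mu = mu,
         yield_biomass = biomass_g_h / ch4_g_h,
         q_ch4 = ch4_mmol_h / denom,
         q_o2 = o2_mmol_h / denom,
         ratio_o2_ch4 = o2_mmol_h / ch4_mmol_h,
         productivity = biomass_g_h * 1000,
         mean_ch4_out_pct = ch4_out, mean_o2_out_pct = o2_out,
         window = window, label = spec$label),
    class = "reeflux_growth_summary")
}

#' @export
print.reeflux_growth_summary <- function(x, ...) {
  cat("steady-state summary [", x$label, "]\n", sep = "")
  cat(sprintf("  mu            : %.3f 1/h\n", x$mu))
  cat(sprintf("  yield         : %.3f g DCW / g CH4\n", x$yield_biomass))
  cat(sprintf("  q(CH4)        : %.2f mmol/gDCW/h\n", x$q_ch4))
  cat(sprintf("  q(O2)         : %.2f mmol/gDCW/h\n", x$q_o2))
  cat(sprintf("  O2:CH4 ratio  : %.2f\n", x$ratio_o2_ch4))
  cat(sprintf("  productivity  : %.1f mg DCW/h\n", x$productivity))
  invisible(x)
}
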