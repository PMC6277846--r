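#' Scan the methanol-fate branch fraction
#'
#' Solves the model once per value of `phi_formate` (the fraction of
#' XoxF-oxidized methanol whose formaldehyde is carried straight through
#' to formate, see [apply_branch_fraction()]) at fixed methane uptake, and
#' optionally prepends a wild-type row (calcium configuration, no `MXALa`
#' branch). Each row reports the O2 consumption rate, the O2:CH4
#' consumption ratio and the growth objective.
#'
#' @param model A lanthanum-configured [stoich_model()] (must contain
#'   `XOXF` and `MXALa`).
#' @param phis Numeric vector of branch fractions in `[0, 1]`.
#' @param ch4_uptake Fixed methane uptake, mmol gDCW^-1 h^-1 (default
#'   11.67).
#' @param wt_model Optional wild-type model for the leading `WT` row
#'   (typically `build_core_model(ca_config(...))`); `NULL` omits the row.
#' @return `data.frame` with columns `scenario`, `phi_formate`, `o2_rate`,
#'   `ratio`, `growth`, `status`. Infeasible values of `phi` are flagged
#'   in `status` and the scan continues.
#' @examples
#' scan_branch_fractions(build_core_model(la_config()),
#'                       phis = c(0.25, 0.5, 0.75, 1),
#'                       wt_model = build_core_model(ca_config()))
#' @export
scan_branch_fractions <- function(model, phis, ch4_uptake = 11.67,
                                  wt_model = NULL) {
  stopifnot(all(phis >= 0), all(phis <= 1))
  rows <- list()
  if (!is.null(wt_model)) {
    s <- solve_fba(wt_model, ch4_uptake = ch4_uptake)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = "WT", phi_formate = NA_real_,
      o2_rate = s$o2_uptake, ratio = s$ratio_o2_ch4,
      growth = s$objective_value, status = s$status,
      stringsAsFactors = FALSE)
  }
  for (phi in phis) {
    s <- solve_fba(apply_branch_fraction(model, phi),
                   ch4_uptake = ch4_uptake)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sprintf("phi=%g", phi), phi_formate = phi,
      o2_rate = s$o2_uptake, ratio = s$ratio_o2_ch4,
      growth = s$objective_value, status = s$status,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Calibrate biomass ATP cost against an observed O2:CH4 ratio
#'
#' The biomass ATP requirement (beta) sets how much of the carbon and
#' reducing power must be respired to power biosynthesis, and hence the
#' O2:CH4 consumption ratio of the solved model. This routine bisects
#' beta until the solved wild-type ratio matches `target_ratio`. The
#' ratio is checked to be monotone non-decreasing in beta over the
#' bracket before bisection.
#'
#' @param model_builder Function `beta -> model`, e.g.
#'   `function(b) build_core_model(ca_config(biomass_atp_cost = b))`.
#' @param target_ratio Target O2:CH4 ratio, in (1, 2).
#' @param beta_range Length-2 search interval (default `c(0, 60)`).
#' @param ch4_uptake Fixed methane uptake during calibration.
#' @param tol Convergence tolerance on the ratio (default 1e-3).
#' @return Calibrated `beta` (scalar) with attributes `ratio` (achieved)
#'   and `growth`.
#' @examples
#' beta <- calibrate_energetics(
#'   function(b) build_core_model(ca_config(biomass_atp_cost = b)),
#'   target_ratio = 1.18)
#' @export
calibrate_energetics <- function(model_builder, target_ratio,
                                 beta_range = c(0, 60),
                                 ch4_uptake = 11.67, tol = 1e-3) {
  stopifnot(is.function(model_builder), length(beta_range) == 2L,
            beta_range[1] < beta_range[2])
  if (!(target_ratio > 1 && target_ratio < 2))
    stop("calibration error: target_ratio must lie in (1, 2)")
  ratio_at <- function(beta) {
    s <- solve_fba(model_builder(beta), ch4_uptake = ch4_uptake,
                   parsimonious = FALSE)
    if (s$status != "optimal")
      stop("calibration error: solve at beta=", beta, " is ", s$status)
    s$ratio_o2_ch4
  }
  lo <- beta_range[1]; hi <- beta_range[2]
  r_lo <- ratio_at(lo); r_hi <- ratio_at(hi)
  if (r_hi < r_lo - 1e-9)
    stop("calibration error: ratio not monotone non-decreasing over range")
  if (target_ratio < r_lo - tol || target_ratio > r_hi + tol)
    stop(sprintf(
      "calibration error: target %.4f outside achievable bracket [%.4f, %.4f]",
      target_ratio, r_lo, r_hi))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r_mid <- ratio_at(mid)
    if (abs(r_mid - target_ratio) < tol) {
      s <- solve_fba(model_builder(mid), ch4_uptake = ch4_uptake)
      return(structure(mid, ratio = r_mid, growth = s$objective_value))
    }
    if (r_mid < target_ratio) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "calibration error: no convergence; achieved bracket [%.4f, %.4f]",
    ratio_at(lo), ratio_at(hi)))
}

#' Branch fraction best matching an observed ratio
#'
#' Picks from a scan the `phi_formate` whose O2:CH4 ratio is closest to
#' an observed consumption ratio; ties break toward the smaller phi.
#'
#' @param scan `data.frame` from [scan_branch_fractions()] (rows with
#'   `NA` phi, e.g. the WT row, are ignored).
#' @param observed_ratio Observed O2:CH4 consumption ratio.
#' @return The best-matching `phi_formate` value.
#' @examples
#' rows <- data.frame(phi_formate = c(0.25, 0.5, 0.75, 1),
#'                    ratio = c(1.28, 1.38, 1.49, 1.64))
#' best_matching_phi(rows, 1.28)
#' @export
best_matching_phi <- function(scan, observed_ratio) {
  stopifnot(is.data.frame(scan), nrow(scan) >= 1L,
            all(c("phi_formate", "ratio") %in% names(scan)))
  rows <- scan[!is.na(scan$phi_formate) & !is.na(scan$ratio), , drop = FALSE]
  if (!nrow(rows)) stop("scan contains no phi rows with solved ratios")
  dev <- abs(rows$ratio - observed_ratio)
  cand <- rows$phi_formate[dev <= min(dev) + 1e-12]
  min(cand)
}
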