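#' Render a branch-fraction scan as a TSV table
#'
#' Formats the output of [scan_branch_fractions()] in the layout of a
#' flux-simulation summary table: one row per scenario with the O2
#' consumption rate and the O2:CH4 consumption ratio at two decimals,
#' the WT row (if present) first.
#'
#' @param rows `data.frame` from [scan_branch_fractions()].
#' @return Character scalar of TSV text (with trailing newline).
#' @export
render_scan_table <- function(rows) {
  if (!is.data.frame(rows) || !nrow(rows))
    stop("scan rows must be a non-empty data.frame")
  stopifnot(all(c("scenario", "o2_rate", "ratio", "growth") %in%
                  names(rows)))
  ord <- order(rows$scenario != "WT")   # WT first, otherwise stable
  rows <- rows[ord, , drop = FALSE]
  body <- sprintf("%s\t%.2f\t%.2f\t%.4f", rows$scenario, rows$o2_rate,
                  rows$ratio, rows$growth)
  paste0(paste(c("scenario\to2_rate\tratio\tgrowth", body),
               collapse = "\n"), "\n")
}

#' Render a growth summary as a TSV block
#'
#' @param summaries One [steady_state_summary()] result or a list of
#'   them (one column per condition).
#' @return Character scalar of TSV text.
#' @export
render_growth_table <- function(summaries) {
  if (inherits(summaries, "reeflux_growth_summary"))
    summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  labs <- vapply(summaries, `[[`, "", "label")
  get <- function(f, d) vapply(summaries, function(s) s[[f]], 0)
  lines <- c(
    paste(c("parameter", labs), collapse = "\t"),
    paste(c("dilution_rate_per_h", sprintf("%.3f", get("mu"))),
          collapse = "\t"),
    paste(c("yield_g_per_gCH4", sprintf("%.3f", get("yield_biomass"))),
          collapse = "\t"),
    paste(c("q_ch4_mmol_gDCW_h", sprintf("%.2f", get("q_ch4"))),
          collapse = "\t"),
    paste(c("q_o2_mmol_gDCW_h", sprintf("%.2f", get("q_o2"))),
          collapse = "\t"),
    paste(c("ratio_o2_ch4", sprintf("%.2f", get("ratio_o2_ch4"))),
          collapse = "\t"),
    paste(c("productivity_mgDCW_h", sprintf("%.1f", get("productivity"))),
          collapse = "\t"))
  paste0(paste(lines, collapse = "\n"), "\n")
}
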