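#' Metabolite set of the core C1 model
#'
#' @return Named list of [metabolite()] objects.
#' @keywords internal
core_metabolites <- function() {
  mets <- list(
    metabolite("ch4",   "methane",      c(C = 1, H = 4)),
    metabolite("o2",    "oxygen",       c(O = 2)),
    metabolite("co2",   "carbon dioxide", c(C = 1, O = 2)),
    metabolite("h2o",   "water",        c(H = 2, O = 1)),
    metabolite("ch3oh", "methanol",     c(C = 1, H = 4, O = 1)),
    metabolite("hcho",  "formaldehyde", c(C = 1, H = 2, O = 1)),
    metabolite("chooh", "formate",      c(C = 1, H = 2, O = 2)),
    metabolite("pyr",   "pyruvate",     c(C = 3, H = 4, O = 3)),
    # bookkeeping pools: protons folded into the lumped P/O parameters;
    # the reduced forms carry the hydrogens needed for H closure
    metabolite("atp",  "ATP",  pseudo = TRUE),
    metabolite("adp",  "ADP",  pseudo = TRUE),
    metabolite("pi",   "phosphate", pseudo = TRUE),
    metabolite("nad",  "NAD+", pseudo = TRUE),
    metabolite("nadh", "NADH", c(H = 2), pseudo = TRUE),
    metabolite("q",    "quinone", pseudo = TRUE),
    metabolite("qh2",  "quinol",  c(H = 2), pseudo = TRUE),
    metabolite("cytm_ox",  "MxaFI-linked cytochrome (oxidized)", pseudo = TRUE),
    metabolite("cytm_red", "MxaFI-linked cytochrome (reduced)", c(H = 1),
               pseudo = TRUE),
    metabolite("cytx_ox",  "XoxF-linked cytochrome (oxidized)", pseudo = TRUE),
    metabolite("cytx_red", "XoxF-linked cytochrome (reduced)", c(H = 1),
               pseudo = TRUE),
    metabolite("biomass", "biomass", c(C = 3), pseudo = TRUE,
               is_exchange_species = TRUE)
  )
  names(mets) <- vapply(mets, `[[`, "", "id")
  mets
}

#' Build the core stoichiometric model of methanotrophic C1 metabolism
#'
#' Constructs the reduced single-compartment model of *M. alcaliphilum*
#' 20Z-type methane metabolism: pMMO methane oxidation, the MxaFI and/or
#' XoxF methanol-oxidation routes (cytochrome-linked), the
#' cytochrome-linked formaldehyde-to-formate branch (`MXALa`, active in the
#' lanthanum configuration), tetrahydromethanopterin-linked formaldehyde
#' oxidation, formate dehydrogenase, a lumped RuMP assimilation reaction to
#' pyruvate, an optional tetrahydrofolate-linked formate reclaim, the
#' electron transport chain with lumped P/O stoichiometry, a biomass
#' equation and a maintenance ATPase.
#'
#' Default flux bounds are 0 to 1000 mmol gDCW^-1 h^-1; exchange reactions
#' are reversible (-1000, 1000) with uptake as negative flux, fixed at
#' solve time by [solve_fba()].
#'
#' @param config An [enzyme_config()]; at least one methanol route active.
#' @return A [stoich_model()] whose `BIOMASS` reaction carries the
#'   objective.
#' @examples
#' m_ca <- build_core_model(ca_config())
#' m_la <- build_core_model(la_config())
#' "MXALa" %in% names(m_la$reactions)
#' @export
build_core_model <- function(config = ca_config()) {
  stopifnot(inherits(config, "reeflux_enzyme_config"))
  if (!config$mxaFI_active && !config$xoxF_active)
    stop("configuration error: no active methanol-oxidation route")

  # plain decimal rendering so arbitrary calibrated values survive the
  # equation grammar (no scientific notation)
  dec <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  pon <- dec(config$po_nadh)
  poc <- dec(config$po_cyt)
  beta <- dec(config$biomass_atp_cost)
  gamma <- dec(config$biomass_nadh_cost)

  rx <- function(id, eq, name = id, lb = 0, ub = 1000, objective = 0,
                 lumped = FALSE) {
    p <- parse_reaction_equation(eq)
    if (p$reversible) lb <- -1000
    reaction(id, p$stoichiometry, name = name, lb = lb, ub = ub,
             objective = objective, lumped = lumped)
  }

  reactions <- list(
    rx("EX_CH4", "ch4 ->", "methane exchange", lb = -1000),
    rx("EX_O2",  "o2 ->",  "oxygen exchange",  lb = -1000),
    rx("EX_CO2", "co2 ->", "carbon dioxide exchange", lb = -1000),
    rx("EX_H2O", "h2o ->", "water exchange", lb = -1000),
    rx("PMMO", "ch4 + o2 + qh2 -> ch3oh + h2o + q",
       "particulate methane monooxygenase")
  )
  if (config$mxaFI_active)
    reactions <- c(reactions, list(
      rx("MXA", "ch3oh + 2 cytm_ox -> hcho + 2 cytm_red",
         "MxaFI methanol dehydrogenase")))
  if (config$xoxF_active)
    reactions <- c(reactions, list(
      rx("XOXF", "ch3oh + 2 cytx_ox -> hcho + 2 cytx_red",
         "XoxF methanol dehydrogenase")))
  if (config$mxala_active) {
    if (!config$xoxF_active)
      stop("configuration error: MXALa requires the XoxF route")
    reactions <- c(reactions, list(
      rx("MXALa", "hcho + h2o + 2 cytx_ox -> chooh + 2 cytx_red",
         "XoxF-linked formaldehyde oxidation to formate")))
  }
  reactions <- c(reactions, list(
    rx("H4MPT", "hcho + nad -> chooh + nadh",
       "H4MPT-linked formaldehyde oxidation (lumped)", lumped = TRUE),
    rx("FDH", "chooh + nad -> co2 + nadh", "formate dehydrogenase"),
    rx("RUMP", "3 hcho + adp + pi + nad -> pyr + atp + nadh",
       "RuMP assimilation to pyruvate (lumped)", lumped = TRUE)
  ))
  if (config$formate_reclaim_active)
    reactions <- c(reactions, list(
      rx("H4F_RECLAIM", "chooh + atp + nadh -> hcho + adp + pi + nad + h2o",
         "H4folate-linked formate reclaim (lumped)", lumped = TRUE)))
  reactions <- c(reactions, list(
    rx("NDH_Q", "nadh + q -> nad + qh2", "NADH:quinone oxidoreductase"),
    rx("ETC_NADH",
       sprintf("nadh + 0.5 o2 + %s adp + %s pi -> nad + h2o + %s atp",
               pon, pon, pon),
       "NADH respiration (lumped ETC)", lumped = TRUE),
    rx("ETC_CYTM",
       sprintf("2 cytm_red + 0.5 o2 + %s adp + %s pi -> 2 cytm_ox + h2o + %s atp",
               poc, poc, poc),
       "MxaFI-cytochrome respiration (lumped ETC)", lumped = TRUE),
    rx("ETC_CYTX",
       sprintf("2 cytx_red + 0.5 o2 + %s adp + %s pi -> 2 cytx_ox + h2o + %s atp",
               poc, poc, poc),
       "XoxF-cytochrome respiration (lumped ETC)", lumped = TRUE)
  ))
  if (config$medh_pmmo_coupling) {
    # reverse electron transfer: MeDH cytochrome pools can recharge the
    # quinol consumed by pMMO (direct MeDH->pMMO electron coupling)
    cyt_q <- list(
      rx("QRED_CYTM", "2 cytm_red + q -> 2 cytm_ox + qh2",
         "cytochrome-to-quinone electron transfer (MxaFI pool)"),
      rx("QRED_CYTX", "2 cytx_red + q -> 2 cytx_ox + qh2",
         "cytochrome-to-quinone electron transfer (XoxF pool)"))
    keep <- c(config$mxaFI_active, config$xoxF_active)
    reactions <- c(reactions, cyt_q[keep])
  }
  biomass_eq <- sprintf(
    "pyr + %s atp + %s nadh -> biomass + %s adp + %s pi + %s nad",
    beta, gamma, beta, beta, gamma)
  # zero energetic costs degenerate gracefully (zero coefficients dropped)
  if (config$biomass_nadh_cost == 0)
    biomass_eq <- sprintf("pyr + %s atp -> biomass + %s adp + %s pi",
                          beta, beta, beta)
  if (config$biomass_atp_cost == 0 && config$biomass_nadh_cost == 0)
    biomass_eq <- "pyr -> biomass"
  reactions <- c(reactions, list(
    rx("BIOMASS", biomass_eq, "biomass equation (lumped)",
       objective = 1, lumped = TRUE),
    rx("NGAM", "atp -> adp + pi", "non-growth-associated maintenance",
       lb = config$maintenance_atp)
  ))

  mets <- core_metabolites()
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  stoich_model(mets[intersect(names(mets), used)], reactions,
               annotations = list(config = unclass(config)))
}
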