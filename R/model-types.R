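#' Create a metabolite
#'
#' A metabolite is a chemical species (or a bookkeeping pseudo-species such
#' as the ATP/ADP pair, redox carriers or biomass) taking part in reactions
#' of a [stoich_model()].
#'
#' @param id Short unique token, e.g. `"ch3oh"`.
#' @param name Free-text name; defaults to `id`.
#' @param formula Named integer vector of elemental composition, e.g.
#'   `c(C = 1, H = 4, O = 1)`. May be empty only when `pseudo = TRUE`.
#'   Pseudo-species may still carry a partial formula (e.g. the reduced
#'   quinol carries two hydrogens) so that element closure can be audited.
#' @param compartment Compartment token; the core model is single-compartment
#'   (`"c"`).
#' @param pseudo Logical; `TRUE` for bookkeeping species exempt from the
#'   formula requirement.
#' @param is_exchange_species Logical; `TRUE` for species whose mass balance
#'   is not enforced (drains such as biomass).
#'
#' @return An object of class `"reeflux_metabolite"`.
#' @export
metabolite <- function(id, name = id, formula = numeric(0),
                       compartment = "c", pseudo = FALSE,
                       is_exchange_species = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  formula <- unlist(formula)
  if (length(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("formula must be a named element->count vector for '", id, "'")
    if (any(formula < 0))
      stop("formula counts must be >= 0 for '", id, "'")
  } else if (!pseudo) {
    stop("metabolite '", id, "' has no formula and is not flagged pseudo")
  }
  structure(
    list(id = id, name = name, formula = formula, compartment = compartment,
         pseudo = isTRUE(pseudo),
         is_exchange_species = isTRUE(is_exchange_species)),
    class = "reeflux_metabolite")
}

#' Create a reaction
#'
#' @param id Short unique token.
#' @param stoichiometry Named numeric vector mapping metabolite ids to signed
#'   coefficients; negative = consumed, positive = produced. Zeros are not
#'   stored.
#' @param name Free-text name.
#' @param lb,ub Flux bounds in mmol gDCW^-1 h^-1.
#' @param objective Objective coefficient (nonzero marks the growth
#'   objective).
#' @param lumped Logical; lumped reactions are exempt from full H/O balance
#'   checks (carbon balance is still enforced).
#'
#' @return An object of class `"reeflux_reaction"`.
#' @export
reaction <- function(id, stoichiometry, name = id, lb = 0, ub = 1000,
                     objective = 0, lumped = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  s <- unlist(stoichiometry)
  if (!length(s) || is.null(names(s)) || any(!nzchar(names(s))))
    stop("reaction '", id, "' needs a non-empty named stoichiometry")
  if (anyDuplicated(names(s)))
    stop("duplicate metabolite in stoichiometry of '", id, "'")
  s <- s[s != 0]
  if (!length(s))
    stop("reaction '", id, "' has only zero coefficients")
  if (lb > ub)
    stop("reaction '", id, "': lower bound ", lb, " exceeds upper bound ", ub)
  structure(
    list(id = id, name = name, stoichiometry = s, lb = lb, ub = ub,
         objective = objective, lumped = isTRUE(lumped)),
    class = "reeflux_reaction")
}

#' Assemble a stoichiometric model
#'
#' The container for flux balance analysis: a set of metabolites, a set of
#' bounded reactions (at least one carrying a nonzero objective for growth
#' simulations), and optional extra linear constraint rows over reaction
#' fluxes.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param extra_constraints List of constraint rows, each a list with
#'   elements `coef` (named numeric over reaction ids), `rel` (one of
#'   `"="`, `"<="`, `">="`) and `rhs` (scalar).
#' @param annotations Free-form named list.
#'
#' @return An object of class `"reeflux_model"`.
#' @export
stoich_model <- function(metabolites, reactions, extra_constraints = list(),
                         annotations = list()) {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  for (ec in extra_constraints) {
    stopifnot(is.list(ec), ec$rel %in% c("=", "<=", ">="))
    missing <- setdiff(names(ec$coef), rxn_ids)
    if (length(missing))
      stop("extra constraint references unknown reaction(s): ",
           paste(missing, collapse = ", "))
  }
  structure(
    list(metabolites = metabolites, reactions = reactions,
         extra_constraints = extra_constraints, annotations = annotations),
    class = "reeflux_model")
}

#' @export
print.reeflux_model <- function(x, ...) {
  nobj <- sum(vapply(x$reactions, function(r) r$objective != 0, TRUE))
  cat("reeflux stoichiometric model:",
      length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,",
      length(x$extra_constraints), "extra constraint row(s),",
      nobj, "objective reaction(s)\n")
  invisible(x)
}

#' Is a reaction an exchange reaction?
#'
#' Exchange reactions move a single species across the system boundary and
#' are exempt from element-balance checks.
#'
#' @param rxn A [reaction()].
#' @return Logical scalar.
#' @export
is_exchange <- function(rxn) length(rxn$stoichiometry) == 1L

#' Stoichiometric matrix of a model
#'
#' Rows are the mass-balanced metabolites (species flagged
#' `is_exchange_species` are omitted), columns the reactions.
#'
#' @param model A [stoich_model()].
#' @return Dense numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model) {
  balanced <- !vapply(model$metabolites, `[[`, TRUE, "is_exchange_species")
  met_ids <- names(model$metabolites)[balanced]
  S <- matrix(0, length(met_ids), length(model$reactions),
              dimnames = list(met_ids, names(model$reactions)))
  for (r in model$reactions) {
    s <- r$stoichiometry
    keep <- names(s) %in% met_ids
    S[names(s)[keep], r$id] <- s[keep]
  }
  S
}

#' Enzyme and energetics configuration for the core model
#'
#' Encodes which methanol-oxidation route is active and the lumped energetic
#' parameters of the electron transport chain and biomass equation. The two
#' routes are the calcium-dependent two-subunit MxaFI methanol dehydrogenase
#' and the lanthanide-dependent single-subunit XoxF enzyme; `mxala_active`
#' additionally enables the cytochrome-linked oxidation of formaldehyde to
#' formate attributed to XoxF (reaction `MXALa`).
#'
#' @param mxaFI_active,xoxF_active,mxala_active,formate_reclaim_active
#'   Logical route switches. At least one methanol route must be active.
#' @param po_nadh ATP formed per NADH oxidized in the respiratory chain
#'   (lumped P/O, default 1.5).
#' @param po_cyt ATP formed per cytochrome pair oxidized (default 1.0).
#' @param biomass_atp_cost ATP consumed per pyruvate drawn into biomass
#'   (beta; calibratable against an observed O2:CH4 ratio, see
#'   [calibrate_energetics()]).
#' @param biomass_nadh_cost NADH consumed per pyruvate drawn into biomass
#'   (gamma, default 0.3).
#' @param maintenance_atp Non-growth-associated ATP drain, lower bound of the
#'   `NGAM` reaction (default 0).
#' @param medh_pmmo_coupling Logical; when `TRUE` (default) the reduced
#'   methanol-dehydrogenase cytochrome pools may reduce the quinone pool
#'   (reactions `QRED_CYTM`/`QRED_CYTX`), modelling electron delivery from
#'   methanol oxidation to the particulate methane monooxygenase. Without
#'   this route every methanol electron pair must be respired and the
#'   O2:CH4 ratio cannot fall below 1.5.
#'
#' @return An object of class `"reeflux_enzyme_config"`.
#' @export
enzyme_config <- function(mxaFI_active = TRUE, xoxF_active = FALSE,
                          mxala_active = FALSE,
                          formate_reclaim_active = FALSE,
                          po_nadh = 1.5, po_cyt = 1.0,
                          biomass_atp_cost = 2.75,
                          biomass_nadh_cost = 0.3,
                          maintenance_atp = 0,
                          medh_pmmo_coupling = TRUE) {
  num <- c(po_nadh = po_nadh, po_cyt = po_cyt,
           biomass_atp_cost = biomass_atp_cost,
           biomass_nadh_cost = biomass_nadh_cost,
           maintenance_atp = maintenance_atp)
  if (any(!is.finite(num)) || any(num < 0))
    stop("energetic parameters must be finite and >= 0")
  structure(
    list(mxaFI_active = isTRUE(mxaFI_active),
         xoxF_active = isTRUE(xoxF_active),
         mxala_active = isTRUE(mxala_active),
         formate_reclaim_active = isTRUE(formate_reclaim_active),
         po_nadh = po_nadh, po_cyt = po_cyt,
         biomass_atp_cost = biomass_atp_cost,
         biomass_nadh_cost = biomass_nadh_cost,
         maintenance_atp = maintenance_atp,
         medh_pmmo_coupling = isTRUE(medh_pmmo_coupling)),
    class = "reeflux_enzyme_config")
}

#' Route presets for the two growth conditions
#'
#' `ca_config()` is the calcium condition (MxaFI route only); `la_config()`
#' is the lanthanum condition (XoxF route with the formaldehyde-to-formate
#' branch and the tetrahydrofolate-linked formate reclaim active).
#'
#' @param ... Passed on to [enzyme_config()]; overrides the preset's
#'   defaults (including the route switches).
#' @return An `"reeflux_enzyme_config"`.
#' @export
ca_config <- function(...) {
  args <- utils::modifyList(
    list(mxaFI_active = TRUE, xoxF_active = FALSE,
         mxala_active = FALSE, formate_reclaim_active = FALSE),
    list(...))
  do.call(enzyme_config, args)
}

#' @rdname ca_config
#' @export
la_config <- function(...) {
  args <- utils::modifyList(
    list(mxaFI_active = FALSE, xoxF_active = TRUE,
         mxala_active = TRUE, formate_reclaim_active = TRUE),
    list(...))
  do.call(enzyme_config, args)
}
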