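SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a model as SBML Level 3 (core + fbc)
#'
#' Emits the subset of SBML understood by [read_sbml_subset()]: species
#' (with `fbc:chemicalFormula` and `boundaryCondition` for drain species),
#' reactions with stoichiometric speciesReferences, global flux-bound
#' parameters referenced via `fbc:lowerFluxBound`/`fbc:upperFluxBound`,
#' and a maximizing `fbc:objective`. Lumped reactions and pseudo-species
#' are tagged through their `metaid` attribute so flags survive a round
#' trip.
#'
#' @param model A [stoich_model()].
#' @param destination File path.
#' @return `destination`, invisibly.
#' @export
write_sbml <- function(model, destination) {
  stopifnot(inherits(model, "reeflux_model"))
  dec <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "reeflux_model",
                             "fbc:strict" = "false")

  comp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "c", constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    f <- m$formula
    sp <- xml2::xml_add_child(
      los, "species", id = m$id, name = m$name, compartment = m$compartment,
      constant = "false", hasOnlySubstanceUnits = "false",
      boundaryCondition = if (m$is_exchange_species) "true" else "false")
    if (length(f))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula",
                         paste0(names(f), f, collapse = ""))
    if (m$pseudo) xml2::xml_set_attr(sp, "metaid", "pseudo")
  }

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  bounds <- unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                     vapply(model$reactions, `[[`, 0, "ub")))
  bound_id <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", dec(v)))
  for (v in bounds)
    xml2::xml_add_child(lop, "parameter", id = bound_id(v), value = dec(v),
                        constant = "true")

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(
      lor, "reaction", id = r$id, name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bound_id(r$lb),
      "fbc:upperFluxBound" = bound_id(r$ub))
    if (r$lumped) xml2::xml_set_attr(rn, "metaid", "lumped")
    s <- r$stoichiometry
    reac <- s[s < 0]
    prod <- s[s > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_along(reac))
        xml2::xml_add_child(lr, "speciesReference", species = names(reac)[i],
                            stoichiometry = dec(-reac[[i]]),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_along(prod))
        xml2::xml_add_child(lp, "speciesReference", species = names(prod)[i],
                            stoichiometry = dec(prod[[i]]),
                            constant = "true")
    }
  }

  obj_rxns <- Filter(function(r) r$objective != 0, model$reactions)
  if (length(obj_rxns)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (r in obj_rxns)
      xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = r$id,
                          "fbc:coefficient" = dec(r$objective))
  }
  xml2::write_xml(doc, destination)
  invisible(destination)
}

#' Read an SBML Level 3 core + fbc model
#'
#' Imports the subset of SBML needed for flux balance analysis: species,
#' reactions with stoichiometry, fbc flux bounds and the active fbc
#' objective. Unsupported constructs (events, rules, kinetic laws) are
#' ignored with a warning. Reactions without fbc bounds default to
#' (-1000, 1000) when declared reversible and (0, 1000) otherwise, with a
#' warning; a missing objective yields an all-zero objective with a
#' warning. Intended both for models written by [write_sbml()] and for
#' externally published genome-scale reconstructions.
#'
#' @param source File path to an SBML file.
#' @return A [stoich_model()].
#' @export
read_sbml_subset <- function(source) {
  doc <- tryCatch(xml2::read_xml(source),
                  error = function(e) stop("cannot read SBML XML: ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  real_ns <- xml2::xml_ns(doc)
  # tolerate other SBML L3 core namespaces (version 2) and fbc versions
  root_ns <- xml2::xml_attr(doc, "xmlns")
  uris <- unlist(real_ns)
  core <- grep("sbml/level3/version[0-9]+/core", uris, value = TRUE)
  fbcv <- grep("sbml/level3/version[0-9]+/fbc", uris, value = TRUE)
  if (length(core)) ns[["s"]] <- core[[1]]
  if (length(fbcv)) ns[["fbc"]] <- fbcv[[1]]

  for (unsupported in c("listOfEvents", "listOfRules"))
    if (length(xml2::xml_find_all(doc, paste0("//s:", unsupported), ns)))
      warning("ignoring unsupported SBML construct: ", unsupported)

  sp_nodes <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) stop("SBML file contains no species")
  mets <- lapply(sp_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    fs <- xml2::xml_attr(n, "fbc:chemicalFormula", ns = ns)
    pseudo <- identical(xml2::xml_attr(n, "metaid"), "pseudo") ||
      is.na(fs) || !nzchar(fs)
    formula <- if (!is.na(fs) && nzchar(fs)) parse_hill_formula(fs)
               else numeric(0)
    metabolite(
      id,
      name = if (is.na(xml2::xml_attr(n, "name"))) id
             else xml2::xml_attr(n, "name"),
      formula = formula,
      compartment = if (is.na(xml2::xml_attr(n, "compartment"))) "c"
                    else xml2::xml_attr(n, "compartment"),
      pseudo = pseudo,
      is_exchange_species =
        identical(xml2::xml_attr(n, "boundaryCondition"), "true"))
  })

  params <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rxn_nodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  if (!length(rxn_nodes)) stop("SBML file contains no reactions")

  obj_nodes <- xml2::xml_find_all(
    doc, "//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  obj <- stats::setNames(
    as.numeric(xml2::xml_attr(obj_nodes, "fbc:coefficient", ns = ns)),
    xml2::xml_attr(obj_nodes, "fbc:reaction", ns = ns))
  if (!length(obj))
    warning("SBML file declares no fbc objective; objective set to zero")

  rxns <- lapply(rxn_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    rev <- identical(xml2::xml_attr(n, "reversible"), "true")
    ref <- function(path, sign) {
      nodes <- xml2::xml_find_all(n, path, ns)
      stats::setNames(
        sign * vapply(nodes, function(x) {
          st <- xml2::xml_attr(x, "stoichiometry")
          if (is.na(st)) 1 else as.numeric(st)
        }, 0),
        xml2::xml_attr(nodes, "species"))
    }
    s <- c(ref("./s:listOfReactants/s:speciesReference", -1),
           ref("./s:listOfProducts/s:speciesReference", +1))
    lb_id <- xml2::xml_attr(n, "fbc:lowerFluxBound", ns = ns)
    ub_id <- xml2::xml_attr(n, "fbc:upperFluxBound", ns = ns)
    if (is.na(lb_id) || is.na(ub_id) ||
        !(lb_id %in% names(pvals)) || !(ub_id %in% names(pvals))) {
      warning("reaction '", id, "' has no fbc bounds; using defaults")
      lb <- if (rev) -1000 else 0
      ub <- 1000
    } else {
      lb <- pvals[[lb_id]]
      ub <- pvals[[ub_id]]
    }
    nm <- xml2::xml_attr(n, "name")
    reaction(id, s, name = if (is.na(nm)) id else nm, lb = lb, ub = ub,
             objective = if (id %in% names(obj)) obj[[id]] else 0,
             lumped = identical(xml2::xml_attr(n, "metaid"), "lumped"))
  })
  stoich_model(mets, rxns)
}
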