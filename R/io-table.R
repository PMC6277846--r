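#' Write / read a model as a plain reaction table
#'
#' The table format is UTF-8 TSV with header
#' `id\tname\tequation\tlb\tub\tobjective`, one reaction per row, followed
#' by a metabolite block introduced by a line `# metabolites` with header
#' `id\tformula\tpseudo`. Lumped reactions carry the suffix `[lumped]` in
#' their name column; exchange species the suffix `[exchange]` in the
#' formula column. Formulas are Hill-style strings (e.g. `C1H4O1`); the
#' decimal separator is `.` and fields are never quoted.
#'
#' `read_model_table(write_model_table(m, f))` is structurally identical to
#' `m` up to floating-point formatting of bounds and coefficients.
#'
#' @param model A [stoich_model()].
#' @param destination,source File path.
#' @return `write_model_table` returns `destination` invisibly;
#'   `read_model_table` returns a [stoich_model()].
#' @export
write_model_table <- function(model, destination) {
  stopifnot(inherits(model, "reeflux_model"))
  dec <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  lines <- c("id\tname\tequation\tlb\tub\tobjective")
  for (r in model$reactions) {
    nm <- r$name
    if (r$lumped) nm <- paste(nm, "[lumped]")
    eq <- format_reaction_equation(r$stoichiometry,
                                   reversible = r$lb < 0 && !is_exchange(r))
    lines <- c(lines, paste(r$id, nm, eq, dec(r$lb), dec(r$ub),
                            dec(r$objective), sep = "\t"))
  }
  lines <- c(lines, "# metabolites", "id\tformula\tpseudo")
  for (m in model$metabolites) {
    f <- m$formula
    fs <- if (length(f)) paste0(names(f), f, collapse = "") else ""
    if (m$is_exchange_species) fs <- paste(fs, "[exchange]")
    lines <- c(lines, paste(m$id, fs, if (m$pseudo) "1" else "0", sep = "\t"))
  }
  writeLines(lines, destination, useBytes = TRUE)
  invisible(destination)
}

#' @rdname write_model_table
#' @export
read_model_table <- function(source) {
  lines <- readLines(source, encoding = "UTF-8")
  sep_at <- which(trimws(lines) == "# metabolites")
  if (length(sep_at) != 1L)
    stop("model table must contain exactly one '# metabolites' line")
  rxn_lines <- lines[seq_len(sep_at - 1L)]
  met_lines <- lines[seq(sep_at + 1L, length(lines))]
  rxn_tab <- utils::read.delim(text = rxn_lines, stringsAsFactors = FALSE,
                               quote = "", colClasses = "character")
  met_tab <- utils::read.delim(text = met_lines, stringsAsFactors = FALSE,
                               quote = "", colClasses = "character")
  need <- c("id", "name", "equation", "lb", "ub", "objective")
  if (!all(need %in% names(rxn_tab)))
    stop("reaction block must have columns: ", paste(need, collapse = ", "))
  if (!all(c("id", "formula", "pseudo") %in% names(met_tab)))
    stop("metabolite block must have columns: id, formula, pseudo")

  mets <- lapply(seq_len(nrow(met_tab)), function(i) {
    fs <- met_tab$formula[i]
    is_ex <- grepl("\\[exchange\\]", fs)
    fs <- trimws(sub("\\[exchange\\]", "", fs))
    formula <- parse_hill_formula(fs)
    metabolite(met_tab$id[i], met_tab$id[i], formula,
               pseudo = met_tab$pseudo[i] %in% c("1", "TRUE", "true"),
               is_exchange_species = is_ex)
  })
  met_ids <- vapply(mets, `[[`, "", "id")

  rxns <- lapply(seq_len(nrow(rxn_tab)), function(i) {
    p <- tryCatch(parse_reaction_equation(rxn_tab$equation[i]),
                  error = function(e)
                    stop("row ", i, " (", rxn_tab$id[i], "): ",
                         conditionMessage(e)))
    unknown <- setdiff(names(p$stoichiometry), met_ids)
    if (length(unknown))
      stop("row ", i, " (", rxn_tab$id[i],
           "): unknown metabolite(s) in equation: ",
           paste(unknown, collapse = ", "))
    lb <- as.numeric(rxn_tab$lb[i])
    ub <- as.numeric(rxn_tab$ub[i])
    if (is.na(lb) || is.na(ub))
      stop("row ", i, " (", rxn_tab$id[i], "): non-numeric bounds")
    lumped <- grepl("\\[lumped\\]", rxn_tab$name[i])
    nm <- trimws(sub("\\[lumped\\]", "", rxn_tab$name[i]))
    reaction(rxn_tab$id[i], p$stoichiometry, name = nm, lb = lb, ub = ub,
             objective = as.numeric(rxn_tab$objective[i]), lumped = lumped)
  })
  stoich_model(mets, rxns)
}

#' Parse a Hill-style elemental formula string
#'
#' @param text e.g. `"C1H4O1"` or `"CH4"`; empty string gives an empty
#'   formula.
#' @return Named numeric vector element -> count.
#' @keywords internal
parse_hill_formula <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  parts <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(text))
    stop("malformed formula string: '", text, "'")
  out <- numeric(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    ct <- sub("^[A-Za-z]+", "", p)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) +
      (if (nzchar(ct)) as.numeric(ct) else 1)
  }
  out
}
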