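#' Audit element balances of a model
#'
#' Carbon balance is enforced on every non-exchange reaction, including
#' lumped ones; other requested elements (typically H and O) are enforced
#' only on non-lumped reactions, since lumped reactions fold several
#' elementary steps (and their water/proton bookkeeping) into one row.
#' Exchange reactions are exempt by construction.
#'
#' @param model A [stoich_model()].
#' @param elements Character vector of element symbols to audit
#'   (default `c("C", "H", "O")`).
#' @return An object of class `"reeflux_balance_report"`: a list with
#'   `imbalances` (named list, per offending reaction an element->net-count
#'   vector), `exempt` (ids of exchange/lumped reactions exempt from the
#'   full check), and `pass` (logical).
#' @examples
#' check_balance(build_core_model(ca_config()), "C")$pass
#' @export
check_balance <- function(model, elements = c("C", "H", "O")) {
  stopifnot(inherits(model, "reeflux_model"), length(elements) >= 1L)
  for (m in model$metabolites)
    if (!length(m$formula) && !m$pseudo)
      stop("metabolite '", m$id, "' has no formula and is not flagged pseudo")

  elem_count <- function(met_id, el) {
    f <- model$metabolites[[met_id]]$formula
    if (el %in% names(f)) f[[el]] else 0
  }
  imbalances <- list()
  exempt <- character(0)
  for (r in model$reactions) {
    if (is_exchange(r)) {
      exempt <- c(exempt, r$id)
      next
    }
    if (r$lumped) exempt <- c(exempt, r$id)
    check_els <- if (r$lumped) intersect(elements, "C") else elements
    if (!length(check_els)) next
    net <- vapply(check_els, function(el) {
      sum(vapply(names(r$stoichiometry),
                 function(m) r$stoichiometry[[m]] * elem_count(m, el), 0))
    }, 0)
    bad <- net[abs(net) > 1e-9]
    if (length(bad)) imbalances[[r$id]] <- bad
  }
  structure(list(imbalances = imbalances, exempt = unique(exempt),
                 pass = length(imbalances) == 0L),
            class = "reeflux_balance_report")
}

#' @export
print.reeflux_balance_report <- function(x, ...) {
  cat("element balance:", if (x$pass) "PASS" else "FAIL", "\n")
  for (id in names(x$imbalances))
    cat("  ", id, ": ",
        paste(names(x$imbalances[[id]]),
              format(x$imbalances[[id]]), sep = " ", collapse = ", "),
        "\n", sep = "")
  cat("  exempt from full check:", length(x$exempt), "reaction(s)\n")
  invisible(x)
}
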