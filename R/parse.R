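#' Parse a reaction equation string
#'
#' Equations follow the grammar
#' `coef? met_id (" + " coef? met_id)* (" -> " | " <-> ") [products]`
#' with positive decimal coefficients (default 1) and mandatory spaces
#' around `->`/`<->` and `+`. Substrates receive negative coefficients,
#' products positive. An irreversible arrow (`->`) implies a lower bound of
#' zero; `<->` marks the reaction reversible. An empty product side is
#' allowed only for irreversible equations (exchange/drain notation).
#'
#' @param text Equation string, e.g. `"ch3oh + 2 cytm_ox -> hcho + 2 cytm_red"`.
#' @return A list with elements `stoichiometry` (named numeric) and
#'   `reversible` (logical).
#' @examples
#' parse_reaction_equation("3 hcho + adp + pi + nad -> pyr + atp + nadh")
#' @export
parse_reaction_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  arrow <- if (grepl(" <-> ", text, fixed = TRUE)) " <-> "
           else if (grepl(" -> ", text, fixed = TRUE)) " -> "
           else if (grepl("<->\\s*$", text)) "<->$trail"
           else if (grepl("->\\s*$", text)) "->$trail"
           else stop("malformed equation (no ' -> ' or ' <-> ' arrow): ", text)
  if (arrow %in% c("<->$trail", "->$trail")) {
    # trailing arrow: empty product side
    reversible <- arrow == "<->$trail"
    sides <- c(sub("\\s*<?->\\s*$", "", text), "")
  } else {
    reversible <- arrow == " <-> "
    sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
    if (length(sides) == 1L) sides <- c(sides, "")
    if (length(sides) != 2L) stop("malformed equation (multiple arrows): ", text)
  }
  if (reversible && (!nzchar(trimws(sides[1])) || !nzchar(trimws(sides[2]))))
    stop("empty side not allowed with '<->': ", text)
  if (!nzchar(trimws(sides[1])))
    stop("empty substrate side: ", text)

  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- strsplit(side, " + ", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (term in terms) {
      term <- trimws(term)
      m <- regmatches(term, regexec(
        "^(?:([0-9]*\\.?[0-9]+)\\s+)?([A-Za-z_][A-Za-z0-9_]*)$", term))[[1]]
      if (!length(m))
        stop("malformed token '", term, "' in equation: ", text)
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      met <- m[3]
      if (met %in% names(out))
        stop("duplicate metabolite '", met, "' on one side of: ", text)
      out[met] <- sign * coef
    }
    out
  }

  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  both <- intersect(names(lhs), names(rhs))
  stoich <- c(lhs, rhs)
  if (length(both)) {
    # net out species appearing on both sides
    for (met in both) {
      net <- lhs[met] + rhs[met]
      stoich <- stoich[names(stoich) != met]
      if (net != 0) stoich[met] <- net
    }
  }
  list(stoichiometry = stoich, reversible = reversible)
}

#' Format a stoichiometry as an equation string
#'
#' Inverse of [parse_reaction_equation()] up to term order (substrates and
#' products are emitted in stoichiometry order).
#'
#' @param stoichiometry Named numeric vector, negative = substrate.
#' @param reversible Logical; emit `<->` instead of `->`.
#' @return Equation string.
#' @export
format_reaction_equation <- function(stoichiometry, reversible = FALSE) {
  fmt <- function(coefs) {
    if (!length(coefs)) return("")
    paste(vapply(seq_along(coefs), function(i) {
      cf <- abs(coefs[[i]])
      if (cf == 1) names(coefs)[i]
      else paste(format(cf, trim = TRUE, scientific = FALSE), names(coefs)[i])
    }, ""), collapse = " + ")
  }
  lhs <- fmt(stoichiometry[stoichiometry < 0])
  rhs <- fmt(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<->" else "->"
  trimws(paste(lhs, arrow, rhs))
}
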