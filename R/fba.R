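#' Flux balance analysis with fixed methane uptake
#'
#' Maximizes the objective reaction subject to steady state (`S v = 0` over
#' mass-balanced species), flux bounds, and any extra constraint rows of
#' the model, with the methane exchange flux fixed to the supplied uptake
#' (both bounds of `EX_CH4` set to `-ch4_uptake`; uptake is negative
#' exchange flux). Among alternate optima the reported flux vector
#' minimizes the total absolute flux at the fixed optimum (two-stage
#' parsimonious solve), which makes solutions reproducible.
#'
#' @param model A [stoich_model()].
#' @param ch4_uptake Methane uptake in mmol gDCW^-1 h^-1 (> 0). Use
#'   `NULL` to leave exchange bounds untouched (e.g. for imported models
#'   without an `EX_CH4` id).
#' @param objective Objective reaction id; default the model's nonzero
#'   objective reaction(s).
#' @param parsimonious Logical; run the second-stage total-flux
#'   minimization (default `TRUE`).
#' @param tol Solver feasibility tolerance (default 1e-9).
#'
#' @return An object of class `"reeflux_flux_solution"`: list with
#'   `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `objective_value`, `fluxes` (named vector), `o2_uptake`,
#'   `ch4_uptake` and `ratio_o2_ch4`. Infeasibility is reported in
#'   `status`, not raised.
#' @examples
#' sol <- solve_fba(build_core_model(ca_config()), ch4_uptake = 11.67)
#' sol$ratio_o2_ch4
#' @export
solve_fba <- function(model, ch4_uptake = NULL, objective = NULL,
                      parsimonious = TRUE, tol = 1e-9) {
  stopifnot(inherits(model, "reeflux_model"))
  rxn_ids <- names(model$reactions)
  if (is.null(objective)) {
    objective <- rxn_ids[vapply(model$reactions,
                                function(r) r$objective != 0, TRUE)]
    if (!length(objective))
      stop("configuration error: model has no objective reaction")
  }
  if (!all(objective %in% rxn_ids))
    stop("configuration error: missing objective reaction(s): ",
         paste(setdiff(objective, rxn_ids), collapse = ", "))

  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  if (!is.null(ch4_uptake)) {
    stopifnot(ch4_uptake > 0)
    if (!"EX_CH4" %in% rxn_ids)
      stop("configuration error: model has no EX_CH4 exchange reaction")
    lb[["EX_CH4"]] <- ub[["EX_CH4"]] <- -ch4_uptake
  }

  S <- stoich_matrix(model)
  obj <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  for (id in objective) obj[id] <- model$reactions[[id]]$objective
  if (all(obj == 0)) obj[objective] <- 1

  constr <- extra_constraint_rows(model, rxn_ids)
  A_eq <- rbind(S, constr$eq)
  b_eq <- c(rep(0, nrow(S)), constr$eq_rhs)
  res <- lp_solve(obj, lb, ub, A_eq = A_eq, b_eq = b_eq,
                  A_le = constr$le, b_le = constr$le_rhs,
                  maximize = TRUE, eps = tol)
  if (res$status != "optimal")
    return(new_flux_solution(res$status, NA_real_,
                             stats::setNames(rep(NA_real_, length(rxn_ids)),
                                             rxn_ids)))
  v <- stats::setNames(res$solution, rxn_ids)
  opt <- res$objective

  if (parsimonious) {
    v2 <- pfba_stage(obj, opt, lb, ub, A_eq, b_eq, constr, tol)
    if (!is.null(v2)) v <- stats::setNames(v2, rxn_ids)
  }
  new_flux_solution("optimal", opt, v)
}

# second stage: minimize sum(|v|) with the objective pinned at its optimum
pfba_stage <- function(obj, opt, lb, ub, A_eq, b_eq, constr, tol) {
  n <- length(obj)
  # v = p - m with p, m >= 0; variable order (p_1..p_n, m_1..m_n)
  split2 <- function(M) if (is.null(M)) NULL else cbind(M, -M)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  lb2 <- rep(0, 2 * n)
  A_eq2 <- rbind(split2(A_eq), c(obj, -obj))
  b_eq2 <- c(b_eq, opt)
  # enforce lb <= p - m <= ub
  A_le2 <- rbind(split2(diag(n)), -split2(diag(n)))
  b_le2 <- c(ub, -lb)
  if (!is.null(constr$le)) {
    A_le2 <- rbind(A_le2, split2(constr$le))
    b_le2 <- c(b_le2, constr$le_rhs)
  }
  res <- lp_solve(rep(1, 2 * n), lb2, ub2, A_eq = A_eq2, b_eq = b_eq2,
                  A_le = A_le2, b_le = b_le2, maximize = FALSE, eps = tol)
  if (res$status != "optimal") return(NULL)
  res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
}

extra_constraint_rows <- function(model, rxn_ids) {
  eq <- NULL; eq_rhs <- numeric(0)
  le <- NULL; le_rhs <- numeric(0)
  for (ec in model$extra_constraints) {
    row <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
    row[names(ec$coef)] <- ec$coef
    if (ec$rel == "=") {
      eq <- rbind(eq, row); eq_rhs <- c(eq_rhs, ec$rhs)
    } else if (ec$rel == "<=") {
      le <- rbind(le, row); le_rhs <- c(le_rhs, ec$rhs)
    } else {
      le <- rbind(le, -row); le_rhs <- c(le_rhs, -ec$rhs)
    }
  }
  list(eq = eq, eq_rhs = eq_rhs, le = le, le_rhs = le_rhs)
}

new_flux_solution <- function(status, objective_value, fluxes) {
  o2 <- if ("EX_O2" %in% names(fluxes)) -fluxes[["EX_O2"]] else NA_real_
  ch4 <- if ("EX_CH4" %in% names(fluxes)) -fluxes[["EX_CH4"]] else NA_real_
  ratio <- if (is.finite(ch4) && ch4 > 0) o2 / ch4 else NA_real_
  structure(
    list(status = status, objective_value = objective_value,
         fluxes = fluxes, o2_uptake = o2, ch4_uptake = ch4,
         ratio_o2_ch4 = ratio),
    class = "reeflux_flux_solution")
}

#' @export
print.reeflux_flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  growth objective : %.4f\n", x$objective_value))
    cat(sprintf("  CH4 uptake       : %.2f mmol/gDCW/h\n", x$ch4_uptake))
    cat(sprintf("  O2 uptake        : %.2f mmol/gDCW/h\n", x$o2_uptake))
    cat(sprintf("  O2:CH4 ratio     : %.2f\n", x$ratio_o2_ch4))
  }
  invisible(x)
}

#' Constrain the methanol-fate branch fraction
#'
#' Adds the linear coupling row `v_MXALa - phi_formate * v_XOXF = 0`: the
#' fraction `phi_formate` of methanol oxidized by XoxF whose formaldehyde
#' is carried straight on to formate by the cytochrome-linked `MXALa`
#' reaction. The input model is not modified.
#'
#' @param model A [stoich_model()] containing reactions `XOXF` and
#'   `MXALa`.
#' @param phi_formate Fraction in `[0, 1]`.
#' @return A new model with one extra constraint row.
#' @export
apply_branch_fraction <- function(model, phi_formate) {
  stopifnot(inherits(model, "reeflux_model"))
  if (!all(c("XOXF", "MXALa") %in% names(model$reactions)))
    stop("configuration error: model must contain reactions XOXF and MXALa")
  if (!is.numeric(phi_formate) || length(phi_formate) != 1L ||
      is.na(phi_formate) || phi_formate < 0 || phi_formate > 1)
    stop("phi_formate must be a single value in [0, 1]")
  model$extra_constraints <- c(
    model$extra_constraints,
    list(list(coef = c(MXALa = 1, XOXF = -phi_formate), rel = "=", rhs = 0,
              label = "branch_fraction")))
  model
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective stays at or above `fraction_of_optimum` times its optimum.
#'
#' @param model A [stoich_model()].
#' @param fraction_of_optimum Value in (0, 1]; default 1.
#' @param ch4_uptake Optional fixed methane uptake (see [solve_fba()]).
#' @return `data.frame` with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, fraction_of_optimum = 1,
                             ch4_uptake = NULL) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  base <- solve_fba(model, ch4_uptake = ch4_uptake, parsimonious = FALSE)
  if (base$status != "optimal")
    stop("flux variability: base problem is ", base$status)
  rxn_ids <- names(model$reactions)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  if (!is.null(ch4_uptake)) lb[["EX_CH4"]] <- ub[["EX_CH4"]] <- -ch4_uptake
  S <- stoich_matrix(model)
  constr <- extra_constraint_rows(model, rxn_ids)
  A_eq <- rbind(S, constr$eq)
  b_eq <- c(rep(0, nrow(S)), constr$eq_rhs)
  obj_row <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  for (id in rxn_ids)
    obj_row[id] <- model$reactions[[id]]$objective
  # objective >= f * optimum  <=>  -obj_row v <= -f*opt
  A_le <- rbind(constr$le, -obj_row)
  b_le <- c(constr$le_rhs,
            -fraction_of_optimum * base$objective_value)
  out <- data.frame(reaction = rxn_ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rxn_ids)) {
    e <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
    e[rxn_ids[i]] <- 1
    lo <- lp_solve(e, lb, ub, A_eq, b_eq, A_le, b_le, maximize = FALSE)
    hi <- lp_solve(e, lb, ub, A_eq, b_eq, A_le, b_le, maximize = TRUE)
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  out
}
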