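# Dense bounded-variable two-phase simplex.
#
# The flux balance problems solved here are small (tens of reactions) but
# highly degenerate (many zero right-hand sides), so the implementation
# uses Bland's anti-cycling rule and refactorizes the basis at every
# pivot, recomputing the basic solution from scratch so no numerical
# drift accumulates. Variables may have finite lower/upper bounds; slack
# variables of inequality rows are [0, Inf).

#' Solve a bounded linear program
#'
#' Maximize (or minimize) `obj' v` subject to `A_eq v = b_eq`,
#' `A_le v <= b_le` and `lb <= v <= ub`.
#'
#' @param obj Objective coefficients.
#' @param lb,ub Variable bounds (finite for structural variables).
#' @param A_eq,b_eq Equality constraints (may be `NULL`).
#' @param A_le,b_le Inequality constraints (may be `NULL`).
#' @param maximize Logical.
#' @param eps Pivot/feasibility tolerance.
#' @return List with `status` ("optimal" | "infeasible" | "unbounded"),
#'   `objective` and `solution`.
#' @keywords internal
lp_solve <- function(obj, lb, ub, A_eq = NULL, b_eq = NULL,
                     A_le = NULL, b_le = NULL, maximize = TRUE,
                     eps = 1e-9) {
  n <- length(obj)
  obj <- as.numeric(obj); lb <- as.numeric(lb); ub <- as.numeric(ub)
  stopifnot(length(lb) == n, length(ub) == n, all(lb <= ub))
  if (!is.null(A_eq) && !nrow(A_eq)) { A_eq <- NULL; b_eq <- numeric(0) }
  if (!is.null(A_le) && !nrow(A_le)) { A_le <- NULL; b_le <- numeric(0) }
  A <- rbind(A_eq, A_le)
  if (is.null(A)) {
    co <- if (maximize) obj else -obj
    v <- ifelse(co > 0, ub, lb)
    return(list(status = "optimal", objective = sum(obj * v), solution = v))
  }
  dimnames(A) <- NULL
  b <- c(if (is.null(A_eq)) numeric(0) else as.numeric(b_eq),
         if (is.null(A_le)) numeric(0) else as.numeric(b_le))
  m <- nrow(A)
  n_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  n_le <- m - n_eq
  if (n_le > 0) {
    Sl <- matrix(0, m, n_le)
    Sl[cbind(n_eq + seq_len(n_le), seq_len(n_le))] <- 1
    A <- cbind(A, Sl)
    lb <- c(lb, rep(0, n_le))
    ub <- c(ub, rep(Inf, n_le))
    obj <- c(obj, rep(0, n_le))
  }
  res <- simplex_bounded(if (maximize) obj else -obj, A, b, lb, ub, eps)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_,
                solution = rep(NA_real_, n)))
  v <- res$x[seq_len(n)]
  list(status = "optimal", objective = sum(obj[seq_len(n)] * v),
       solution = v)
}

# maximize cc'x s.t. A x = b, lb <= x <= ub (Inf allowed in ub)
simplex_bounded <- function(cc, A, b, lb, ub, eps = 1e-9,
                            max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  # artificial variables give the starting identity basis
  x0 <- ifelse(is.finite(lb), lb, 0)
  r <- b - as.numeric(A %*% x0)
  A <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lb <- c(lb, rep(0, m))
  ub <- c(ub, rep(Inf, m))
  art <- n + seq_len(m)
  basis <- art
  at_upper <- rep(FALSE, n + m)
  ntot <- n + m

  run_phase <- function(cost, basis, at_upper) {
    x <- numeric(ntot)
    for (it in seq_len(max_iter)) {
      nonbasic <- setdiff(seq_len(ntot), basis)
      x[nonbasic] <- ifelse(at_upper[nonbasic], ub[nonbasic], lb[nonbasic])
      B <- A[, basis, drop = FALSE]
      xB <- tryCatch(
        solve(B, b - as.numeric(A[, nonbasic, drop = FALSE] %*% x[nonbasic])),
        error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular"))
      x[basis] <- xB
      y <- solve(t(B), cost[basis])
      d <- cost[nonbasic] - as.numeric(t(A[, nonbasic, drop = FALSE]) %*% y)
      fav <- (!at_upper[nonbasic] & d > eps) |
             (at_upper[nonbasic] & d < -eps)
      if (!any(fav))
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper))
      j <- min(nonbasic[fav])                       # Bland's rule
      sigma <- if (at_upper[j]) -1 else 1
      w <- sigma * as.numeric(solve(B, A[, j]))
      # ratio test: entering variable's own span, then basic bounds
      t_best <- if (is.finite(ub[j]) && is.finite(lb[j])) ub[j] - lb[j]
                else Inf
      leave <- 0L; leave_to_upper <- FALSE
      for (k in seq_len(m)) {
        bi <- basis[k]
        tk <- NA_real_; to_upper <- FALSE
        if (w[k] > eps) {
          tk <- (x[bi] - lb[bi]) / w[k]
        } else if (w[k] < -eps && is.finite(ub[bi])) {
          tk <- (x[bi] - ub[bi]) / w[k]
          to_upper <- TRUE
        }
        if (!is.na(tk)) {
          tk <- max(tk, 0)
          if (tk < t_best - eps ||
              (tk < t_best + eps && leave > 0L && bi < basis[leave])) {
            t_best <- tk; leave <- k; leave_to_upper <- to_upper
          } else if (tk < t_best + eps && leave == 0L && tk <= t_best) {
            t_best <- tk; leave <- k; leave_to_upper <- to_upper
          }
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]                 # bound flip
      } else {
        bi <- basis[leave]
        at_upper[bi] <- leave_to_upper
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
    }
    list(status = "maxiter")
  }

  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, basis, at_upper)
  if (ph1$status != "optimal") return(list(status = "infeasible"))
  if (sum(ph1$x[art]) > 1e-7) return(list(status = "infeasible"))
  ub[art] <- 0                                      # freeze artificials
  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, ph1$at_upper)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status != "optimal") return(list(status = "infeasible"))
  list(status = "optimal", x = ph2$x[seq_len(n)])
}
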