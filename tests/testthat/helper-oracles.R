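# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation.

# LP oracle: enumerate all vertices of {S v = 0, lb <= v <= ub} by fixing
# (n - rank(S)) variables at bounds and solving for the rest; return the
# best objective value. Only usable for tiny networks.
vertex_enumeration_optimum <- function(obj, lb, ub, S, tol = 1e-8) {
  n <- length(obj)
  r <- qr(S)$rank
  nfix <- n - r
  best <- -Inf
  if (nfix == 0L) {
    v <- qr.solve(S, rep(0, nrow(S)))
    if (all(v >= lb - tol & v <= ub + tol)) best <- sum(obj * v)
    return(best)
  }
  for (J in utils::combn(n, nfix, simplify = FALSE)) {
    K <- setdiff(seq_len(n), J)
    SK <- S[, K, drop = FALSE]
    if (qr(SK)$rank < length(K)) next
    for (mask in 0:(2^nfix - 1)) {
      fixed <- ifelse(bitwAnd(mask, 2^(seq_len(nfix) - 1)) > 0,
                      ub[J], lb[J])
      rhs <- -as.numeric(S[, J, drop = FALSE] %*% fixed)
      vK <- tryCatch(qr.solve(SK, rhs), error = function(e) NULL)
      if (is.null(vK)) next
      if (max(abs(SK %*% vK - rhs)) > tol) next
      v <- numeric(n); v[J] <- fixed; v[K] <- vK
      if (all(v >= lb - tol & v <= ub + tol))
        best <- max(best, sum(obj * v))
    }
  }
  best
}

# Brute-force Benjamini-Hochberg step-up from the definition.
bh_stepup_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Brute-force Spearman permutation p-value: full enumeration of orderings.
spearman_perm_bruteforce <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(x, y, method = "spearman")
  rx <- rank(x); ry <- rank(y)
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# Tiny toy model: EX_A (uptake up to 10), A -> B, B -> out (objective).
toy_chain_model <- function() {
  mets <- list(metabolite("a", pseudo = TRUE),
               metabolite("b", pseudo = TRUE))
  rxns <- list(
    reaction("EX_A", c(a = -1), lb = -10, ub = 0),
    reaction("A2B", c(a = -1, b = 1), lb = 0, ub = 1000),
    reaction("SINK_B", c(b = -1), lb = 0, ub = 1000, objective = 1))
  stoich_model(mets, rxns)
}

# Two redundant parallel routes from A to B plus a sink.
toy_parallel_model <- function() {
  mets <- list(metabolite("a", pseudo = TRUE),
               metabolite("b", pseudo = TRUE))
  rxns <- list(
    reaction("EX_A", c(a = -1), lb = -10, ub = 0),
    reaction("R1", c(a = -1, b = 1), lb = 0, ub = 1000),
    reaction("R2", c(a = -1, b = 1), lb = 0, ub = 1000),
    reaction("SINK_B", c(b = -1), lb = 0, ub = 1000, objective = 1))
  stoich_model(mets, rxns)
}

expect_model_equivalent <- function(m1, m2) {
  expect_setequal(names(m1$reactions), names(m2$reactions))
  expect_setequal(names(m1$metabolites), names(m2$metabolites))
  for (id in names(m1$reactions)) {
    r1 <- m1$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_equal(sort(names(r1$stoichiometry)),
                 sort(names(r2$stoichiometry)), info = id)
    expect_equal(r1$stoichiometry[sort(names(r1$stoichiometry))],
                 r2$stoichiometry[sort(names(r2$stoichiometry))],
                 info = id)
    expect_equal(r1$lb, r2$lb, info = id)
    expect_equal(r1$ub, r2$ub, info = id)
    expect_equal(r1$objective, r2$objective, info = id)
    expect_equal(r1$lumped, r2$lumped, info = id)
  }
  for (id in names(m1$metabolites)) {
    a <- m1$metabolites[[id]]; b <- m2$metabolites[[id]]
    expect_equal(sort(names(a$formula)), sort(names(b$formula)), info = id)
    if (length(a$formula))
      expect_equal(a$formula[sort(names(a$formula))],
                   b$formula[sort(names(b$formula))], info = id)
    expect_equal(a$pseudo, b$pseudo, info = id)
    expect_equal(a$is_exchange_species, b$is_exchange_species, info = id)
  }
}
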