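test_that("FBA propagates bounds through a toy chain", {
  sol <- solve_fba(toy_chain_model())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes[["A2B"]]), 10)
  expect_equal(unname(sol$fluxes[["EX_A"]]), -10)
})

test_that("FBA optimum matches the vertex-enumeration oracle on small networks", {
  models <- list(toy_chain_model(), toy_parallel_model())
  # a reversible/irreversible mixed 5-reaction network
  mets <- list(metabolite("a", pseudo = TRUE),
               metabolite("b", pseudo = TRUE),
               metabolite("c", pseudo = TRUE))
  models[[3]] <- stoich_model(mets, list(
    reaction("EX_A", c(a = -1), lb = -7, ub = 0),
    reaction("R1", c(a = -1, b = 1), lb = 0, ub = 4),
    reaction("R2", c(a = -1, c = 1), lb = -3, ub = 1000),
    reaction("R3", c(b = -1, c = 1), lb = -1000, ub = 1000),
    reaction("SINK_C", c(c = -1), lb = 0, ub = 1000, objective = 1)))
  for (m in models) {
    sol <- solve_fba(m, parsimonious = FALSE)
    lb <- vapply(m$reactions, `[[`, 0, "lb")
    ub <- vapply(m$reactions, `[[`, 0, "ub")
    obj <- vapply(m$reactions, `[[`, 0, "objective")
    oracle <- vertex_enumeration_optimum(obj, lb, ub, stoich_matrix(m))
    expect_equal(sol$objective_value, oracle, tolerance = 1e-7)
  }
})

test_that("steady-state fluxes satisfy S v = 0 and bounds at the optimum", {
  m <- build_core_model(la_config())
  sol <- solve_fba(apply_branch_fraction(m, 0.25), ch4_uptake = 11.67)
  expect_equal(sol$status, "optimal")
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-7)
  lb <- vapply(m$reactions, `[[`, 0, "lb")
  ub <- vapply(m$reactions, `[[`, 0, "ub")
  lb[["EX_CH4"]] <- ub[["EX_CH4"]] <- -11.67
  expect_true(all(sol$fluxes >= lb - 1e-7 & sol$fluxes <= ub + 1e-7))
})

test_that("full oxidation closes electron balance at an O2:CH4 ratio of exactly 2", {
  m <- build_core_model(ca_config(maintenance_atp = 0.5))
  m$reactions$BIOMASS$ub <- 0
  sol <- solve_fba(m, ch4_uptake = 11.67)
  expect_equal(sol$ratio_o2_ch4, 2, tolerance = 1e-9)
  expect_equal(unname(-sol$fluxes[["EX_CO2"]]), -11.67, tolerance = 1e-7)
})

test_that("with growth enabled the O2:CH4 ratio lies strictly between 1 and 2", {
  for (cfg in list(ca_config(), la_config(),
                   ca_config(biomass_atp_cost = 0.5),
                   ca_config(biomass_atp_cost = 20))) {
    sol <- solve_fba(build_core_model(cfg), ch4_uptake = 11.67)
    expect_gt(sol$ratio_o2_ch4, 1)
    expect_lt(sol$ratio_o2_ch4, 2)
    expect_gt(sol$objective_value, 0)
  }
})

test_that("branch fraction coupling forces the planted MXALa/XOXF flux ratio", {
  m <- build_core_model(la_config())
  s0 <- solve_fba(apply_branch_fraction(m, 0), ch4_uptake = 11.67)
  expect_equal(unname(s0$fluxes[["MXALa"]]), 0, tolerance = 1e-8)
  s5 <- solve_fba(apply_branch_fraction(m, 0.5), ch4_uptake = 11.67)
  expect_equal(unname(s5$fluxes[["MXALa"]]),
               0.5 * unname(s5$fluxes[["XOXF"]]), tolerance = 1e-7)
  expect_error(apply_branch_fraction(m, 1.2), "\\[0, 1\\]")
  expect_error(apply_branch_fraction(build_core_model(ca_config()), 0.5),
               "configuration error")
})

test_that("full formate diversion without reclaim abolishes growth", {
  m <- build_core_model(la_config(formate_reclaim_active = FALSE))
  sol <- solve_fba(apply_branch_fraction(m, 1), ch4_uptake = 11.67)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-8)
})

test_that("solved ratio increases with phi and with the biomass ATP cost", {
  m <- build_core_model(la_config())
  ratios <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(phi) {
    solve_fba(apply_branch_fraction(m, phi), ch4_uptake = 11.67,
              parsimonious = FALSE)$ratio_o2_ch4
  }, 0)
  expect_true(all(diff(ratios) > 0))
  betas <- c(1, 3, 6, 12, 24)
  rb <- vapply(betas, function(b) {
    solve_fba(build_core_model(ca_config(biomass_atp_cost = b)),
              ch4_uptake = 11.67, parsimonious = FALSE)$ratio_o2_ch4
  }, 0)
  expect_true(all(diff(rb) >= -1e-9))
})

test_that("doubling methane uptake scales fluxes linearly and leaves the ratio unchanged", {
  m <- build_core_model(la_config())
  s1 <- solve_fba(m, ch4_uptake = 11.67)
  s2 <- solve_fba(m, ch4_uptake = 23.34)
  expect_equal(s2$o2_uptake, 2 * s1$o2_uptake, tolerance = 1e-6)
  expect_equal(s2$objective_value, 2 * s1$objective_value,
               tolerance = 1e-6)
  expect_equal(s2$ratio_o2_ch4, s1$ratio_o2_ch4, tolerance = 1e-8)
})

test_that("scan rows are ordered, flagged on infeasibility, and include the WT row", {
  la <- build_core_model(la_config())
  wt <- build_core_model(ca_config())
  rows <- scan_branch_fractions(la, c(0.25, 0.5, 0.75, 1),
                                wt_model = wt)
  expect_equal(nrow(rows), 5)
  expect_equal(rows$scenario[1], "WT")
  expect_true(all(diff(rows$ratio[-1]) > 0))
  expect_lt(rows$ratio[1], min(rows$ratio[-1]))
  # o2_rate / ratio is the fixed methane uptake in every solved row
  expect_equal(rows$o2_rate / rows$ratio, rep(11.67, 5), tolerance = 1e-6)

  # infeasible rows are flagged and do not abort the scan
  la_blocked <- build_core_model(la_config(formate_reclaim_active = FALSE))
  la_blocked$reactions$H4MPT$ub <- 0   # formate cannot re-enter or burn
  la_blocked$reactions$FDH$ub <- 0
  rows2 <- scan_branch_fractions(la_blocked, c(0, 0.5))
  expect_equal(nrow(rows2), 2)
  expect_true("infeasible" %in% rows2$status)
})

test_that("phi = 0 coincides with the unconstrained model when MXALa carries no optimal flux", {
  m <- build_core_model(la_config())
  free <- solve_fba(m, ch4_uptake = 11.67)
  tied <- solve_fba(apply_branch_fraction(m, 0), ch4_uptake = 11.67)
  if (abs(free$fluxes[["MXALa"]]) < 1e-8)
    expect_equal(tied$objective_value, free$objective_value,
                 tolerance = 1e-7)
})

test_that("energetic calibration hits target ratios and fails cleanly outside range", {
  builder <- function(b) build_core_model(ca_config(biomass_atp_cost = b))
  beta18 <- calibrate_energetics(builder, 1.18)
  expect_lt(abs(attr(beta18, "ratio") - 1.18), 1e-3)
  beta12 <- calibrate_energetics(builder, 1.12)
  expect_lt(abs(attr(beta12, "ratio") - 1.12), 1e-3)
  expect_lt(as.numeric(beta12), as.numeric(beta18))
  expect_error(calibrate_energetics(builder, 2.5), "calibration error")
  expect_error(calibrate_energetics(builder, 1.9999,
                                    beta_range = c(0, 10)),
               "calibration error")
})

test_that("flux variability brackets alternate optima correctly", {
  fva1 <- flux_variability(toy_chain_model(), 1)
  expect_true(all(abs(fva1$max - fva1$min) < 1e-7))

  fva2 <- flux_variability(toy_parallel_model(), 1)
  r1 <- fva2[fva2$reaction == "R1", ]
  expect_equal(r1$min, 0, tolerance = 1e-7)
  expect_equal(r1$max, 10, tolerance = 1e-7)

  fva3 <- flux_variability(toy_chain_model(), 0.9)
  whole <- merge(fva1, fva3, by = "reaction",
                 suffixes = c("_tight", "_relaxed"))
  expect_true(all(whole$min_relaxed <= whole$min_tight + 1e-7))
  expect_true(all(whole$max_relaxed >= whole$max_tight - 1e-7))
})

test_that("best-matching phi follows nearest ratio with ties toward smaller phi", {
  rows <- data.frame(phi_formate = c(0.25, 0.5, 0.75, 1),
                     ratio = c(1.28, 1.38, 1.49, 1.64))
  expect_equal(best_matching_phi(rows, 1.28), 0.25)
  expect_equal(best_matching_phi(rows, 2.0), 1.0)
  tie <- data.frame(phi_formate = c(0.2, 0.8), ratio = c(1.2, 1.4))
  expect_equal(best_matching_phi(tie, 1.3), 0.2)
})

test_that("infeasible and missing-objective problems are reported, not crashed", {
  m <- toy_chain_model()
  m$reactions$A2B$ub <- 5
  m$reactions$EX_A$ub <- -8   # force more uptake than the chain passes
  sol <- solve_fba(m)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
  m2 <- toy_chain_model()
  expect_error(solve_fba(m2, objective = "NOPE"), "configuration error")
})
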