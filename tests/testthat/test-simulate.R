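test_that("generators are reproducible given a seed and differ across seeds", {
  cond <- default_conditions()$la_optimal
  a <- simulate_offgas(cond$spec, cond$yield_biomass, 1.28, seed = 4)
  b <- simulate_offgas(cond$spec, cond$yield_biomass, 1.28, seed = 4)
  c <- simulate_offgas(cond$spec, cond$yield_biomass, 1.28, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$ch4_out_pct, c$ch4_out_pct))

  s1 <- suppressWarnings(simulate_counts(n_features = 200, seed = 3))
  s2 <- suppressWarnings(simulate_counts(n_features = 200, seed = 3))
  expect_identical(s1$counts, s2$counts)

  p1 <- simulate_spectral_counts(n_proteins = 50, seed = 3)
  p2 <- simulate_spectral_counts(n_proteins = 50, seed = 3)
  expect_identical(p1$counts, p2$counts)

  m1 <- simulate_metabolites(seed = 3)
  m2 <- simulate_metabolites(seed = 3)
  expect_identical(m1$abundances, m2$abundances)
})

test_that("every generated dataset carries its planted ground truth sidecar", {
  cond <- default_conditions()$la_optimal
  og <- simulate_offgas(cond$spec, cond$yield_biomass, 1.28, seed = 1)
  expect_equal(attr(og, "truth")$ratio_o2_ch4, 1.28)
  expect_equal(attr(og, "truth")$yield_biomass, cond$yield_biomass)

  sim <- suppressWarnings(simulate_counts(n_features = 100, seed = 1))
  expect_equal(sim$truth$fold_change[sim$truth$feature_id == "xoxF"], 4)
  expect_equal(sim$truth$fold_change[sim$truth$feature_id == "fae2"], 14)
  expect_equal(
    sim$truth$fold_change[sim$truth$feature_id == "sulfate_transporter"],
    70)
  expect_true(all(sim$truth$fold_change > 0))
})

test_that("the default effect registry encodes the hallmark switch responses", {
  reg <- default_effect_registry()
  fc <- function(id) reg$transcript_fc[reg$feature_id == id]
  expect_equal(fc("xoxF"), 4)
  expect_equal(fc("fae2"), 14)
  expect_equal(fc("sulfate_transporter"), 70)
  expect_equal(fc("mxaF"), 1 / 20)
  expect_equal(fc("xoxG4"), 1 / 1.5)
  expect_equal(reg$protein_fc[reg$feature_id == "xoxG4"], 1)
  expect_equal(reg$direction[reg$feature_id == "mxaG"], "down")
  # overriding an entry replaces it
  reg2 <- default_effect_registry(
    extra = data.frame(feature_id = "xoxF", transcript_fc = 2,
                       protein_fc = 2))
  expect_equal(reg2$transcript_fc[reg2$feature_id == "xoxF"], 2)
  expect_equal(sum(reg2$feature_id == "xoxF"), 1)
})

test_that("zero-dispersion counts behave like Poisson and recover the largest effect", {
  est <- vapply(1:10, function(s) {
    sim <- suppressWarnings(
      simulate_counts(n_features = 500, dispersion = 0, seed = s))
    ca <- rowMeans(sim$counts[, sim$condition == "Ca"])
    la <- rowMeans(sim$counts[, sim$condition == "La"])
    unname(la["sulfate_transporter"] / ca["sulfate_transporter"])
  }, 0)
  expect_lt(abs(mean(est) - 70) / 70, 0.2)
})

test_that("an all-neutral registry yields about the nominal false-positive rate", {
  neutral <- default_effect_registry()
  neutral$transcript_fc[] <- 1
  neutral$protein_fc[] <- 1
  calls <- unlist(lapply(1:5, function(s) {
    sim <- simulate_counts(n_features = 400, registry = neutral, seed = s)
    de <- call_deg(simple_de_table(sim$counts, sim$condition),
                   lfc_threshold = 0, alpha = 0.05)
    de$call != "ns"
  }))
  expect_lt(mean(calls), 0.1)   # Welch t on n=2 is conservative/noisy
})

test_that("planted protein effects are flagged by the twofold spectral rule", {
  sp <- simulate_spectral_counts(seed = 21)
  sfc <- spectral_fold_changes(sp$counts, sp$condition)
  truth <- sp$truth
  get_dir <- function(id) sfc$direction[sfc$protein_id == id]
  expect_equal(get_dir("mxaF"), "down")
  expect_equal(get_dir("xoxG4"), "ns")
  planted <- truth$feature_id[truth$fold_change > 2 |
                                truth$fold_change < 0.5]
  expect_gte(mean(sfc$significant[sfc$protein_id %in% planted]), 0.95)
  # neutral planted proteins rarely cross the rule
  neutral <- sfc$protein_id %in%
    truth$feature_id[truth$fold_change == 1]
  expect_lt(mean(sfc$significant[neutral]), 0.05)
})

test_that("noiseless metabolite tables return exactly the planted effects", {
  sim <- simulate_metabolites(noise_sd = 0, seed = 8)
  out <- metabolite_log_ratios(sim$abundances, sim$condition)
  expect_equal(
    out$log2_ratio[match(sim$truth$metabolite, out$metabolite)],
    sim$truth$log2_effect, tolerance = 1e-10)
})

test_that("metabolite direction recovery exceeds 90% at defaults", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_metabolites(seed = s)
    out <- metabolite_log_ratios(sim$abundances, sim$condition)
    truth <- sim$truth[match(out$metabolite, sim$truth$metabolite), ]
    changed <- truth$log2_effect != 0
    mean(sign(out$log2_ratio[changed]) == sign(truth$log2_effect[changed]))
  }, 0)
  expect_gte(mean(hits), 0.9)
})

test_that("synthetic replicates reproduce the high replicate correlation of the design", {
  rs <- vapply(1:5, function(s) {
    sim <- simulate_counts(seed = s)
    min(replicate_correlation(
      sim$counts[, sim$condition == "Ca"])$pearson_r,
      replicate_correlation(
        sim$counts[, sim$condition == "La"])$pearson_r)
  }, 0)
  expect_true(all(rs > 0.98))
})

test_that("off-gas generator rejects parameters implying negative outlet gas", {
  spec <- condition_spec("bad", inlet_ch4_pct = 0.2, inlet_o2_pct = 5,
                         gas_flow = 0.2, biomass_conc = 0.75,
                         dilution_rate = 0.07)
  expect_error(simulate_offgas(spec, 0.64, 1.28, seed = 1),
               "parameter error")
})
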