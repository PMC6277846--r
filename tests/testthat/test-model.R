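test_that("reaction equations parse per the grammar", {
  p <- parse_reaction_equation("ch4 + o2 + qh2 -> ch3oh + h2o + q")
  expect_length(p$stoichiometry, 6)
  expect_false(p$reversible)
  expect_equal(p$stoichiometry[["ch4"]], -1)
  expect_equal(p$stoichiometry[["ch3oh"]], 1)

  p2 <- parse_reaction_equation(
    "3 hcho + adp + pi + nad -> pyr + atp + nadh + h2o")
  expect_equal(p2$stoichiometry[["hcho"]], -3)
  expect_equal(p2$stoichiometry[["h2o"]], 1)

  p3 <- parse_reaction_equation("a <-> b")
  expect_true(p3$reversible)

  expect_error(parse_reaction_equation("a <-> "), "empty side")
  expect_error(parse_reaction_equation("a + a -> b"), "duplicate")
  expect_error(parse_reaction_equation("2x -> b"), "malformed token")
  expect_error(parse_reaction_equation("a b"), "arrow")
})

test_that("equation formatting round-trips through the parser", {
  eqs <- c("ch4 + o2 + qh2 -> ch3oh + h2o + q",
           "3 hcho + adp + pi + nad -> pyr + atp + nadh",
           "a <-> b",
           "0.5 x + 1.5 y -> z")
  for (eq in eqs) {
    p <- parse_reaction_equation(eq)
    q <- parse_reaction_equation(
      format_reaction_equation(p$stoichiometry, p$reversible))
    expect_equal(sort(names(p$stoichiometry)), sort(names(q$stoichiometry)))
    expect_equal(p$stoichiometry[sort(names(p$stoichiometry))],
                 q$stoichiometry[sort(names(q$stoichiometry))])
    expect_equal(p$reversible, q$reversible)
  }
})

test_that("route configuration controls which reactions are built", {
  m_ca <- build_core_model(ca_config())
  expect_true("MXA" %in% names(m_ca$reactions))
  expect_false("MXALa" %in% names(m_ca$reactions))
  expect_false("XOXF" %in% names(m_ca$reactions))

  m_la <- build_core_model(la_config())
  expect_true(all(c("XOXF", "MXALa", "H4F_RECLAIM") %in%
                    names(m_la$reactions)))
  expect_false("MXA" %in% names(m_la$reactions))

  expect_error(build_core_model(
    enzyme_config(mxaFI_active = FALSE, xoxF_active = FALSE)),
    "configuration error")
  expect_error(enzyme_config(po_nadh = -1), "must be finite and >= 0")
})

test_that("core model passes carbon balance everywhere and full H/O on non-lumped reactions", {
  for (cfg in list(ca_config(), la_config())) {
    rep <- check_balance(build_core_model(cfg), c("C", "H", "O"))
    expect_true(rep$pass)
  }
  # a hand count of pMMO: the quinol pair carries the two hydrogens
  m <- build_core_model(ca_config())
  pmmo <- m$reactions$PMMO$stoichiometry
  h_net <- sum(pmmo * vapply(names(pmmo), function(id) {
    f <- m$metabolites[[id]]$formula
    if ("H" %in% names(f)) f[["H"]] else 0
  }, 0))
  expect_equal(h_net, 0)
})

test_that("balance audit reports a constructed defect with the right element and size", {
  m <- build_core_model(la_config())
  s <- m$reactions$MXALa$stoichiometry
  m$reactions$MXALa$stoichiometry <- s[names(s) != "h2o"]
  rep <- check_balance(m, c("C", "H", "O"))
  expect_false(rep$pass)
  expect_true("MXALa" %in% names(rep$imbalances))
  # removing the water reactant leaves one excess O and two excess H on
  # the product side
  expect_equal(unname(rep$imbalances$MXALa[["O"]]), 1)
  expect_equal(unname(rep$imbalances$MXALa[["H"]]), 2)
})

test_that("balance check rejects unflagged formula-less metabolites", {
  mets <- list(metabolite("x", formula = c(C = 1)),
               metabolite("bad", pseudo = TRUE))
  mets[[2]]$pseudo <- FALSE   # simulate a corrupted flag
  rxns <- list(reaction("R", c(x = -1, bad = 1)))
  m <- stoich_model(mets, rxns)
  expect_error(check_balance(m, "C"), "not flagged pseudo")
})

test_that("model table writer and reader are mutually inverse", {
  for (m in list(build_core_model(ca_config()),
                 build_core_model(la_config()))) {
    f <- withr::local_tempfile(fileext = ".tsv")
    write_model_table(m, f)
    expect_model_equivalent(m, read_model_table(f))
  }
})

test_that("hand-written table files load and invalid ones are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tname\tequation\tlb\tub\tobjective",
    "EX_A\tuptake\ta ->\t-10\t0\t0",
    "A2B\tconvert\ta -> b\t0\t1000\t0",
    "SINK\tsink\tb ->\t0\t1000\t1",
    "# metabolites",
    "id\tformula\tpseudo",
    "a\t\t1",
    "b\t\t1"), f)
  m <- read_model_table(f)
  expect_length(m$reactions, 3)
  sol <- solve_fba(m, objective = "SINK")
  expect_equal(sol$objective_value, 10)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tname\tequation\tlb\tub\tobjective",
    "R\tr\ta -> b\t5\t1\t0",
    "# metabolites", "id\tformula\tpseudo", "a\t\t1", "b\t\t1"), f2)
  expect_error(read_model_table(f2), "bound")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tname\tequation\tlb\tub\tobjective",
    "R\tr\ta -> zz\t0\t1\t0",
    "# metabolites", "id\tformula\tpseudo", "a\t\t1"), f3)
  expect_error(read_model_table(f3), "unknown metabolite")
})

test_that("SBML writer and subset reader round-trip the core model", {
  m <- build_core_model(la_config())
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml_subset(f)
  expect_model_equivalent(m, m2)
  s1 <- solve_fba(m, 11.67)
  s2 <- solve_fba(m2, 11.67)
  expect_equal(s1$objective_value, s2$objective_value, tolerance = 1e-9)
})

test_that("minimal and degenerate SBML inputs are handled", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mini"><listOfSpecies>',
    '<species id="s1" compartment="c" constant="false"/>',
    '<species id="s2" compartment="c" constant="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="r1" reversible="false">',
    '<listOfReactants><speciesReference species="s1" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="s2" stoichiometry="1"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), f)
  expect_warning(expect_warning(m <- read_sbml_subset(f), "no fbc bounds"),
                 "no fbc objective")
  expect_length(m$reactions, 1)
  expect_equal(m$reactions$r1$lb, 0)
  expect_equal(m$reactions$r1$ub, 1000)
  expect_equal(m$reactions$r1$objective, 0)

  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not xml <", f2)
  expect_error(read_sbml_subset(f2), "cannot read SBML XML")
})
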