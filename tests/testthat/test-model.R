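test_that("constructors enforce the structural invariants", {
  expect_error(reaction("r", numeric()), "empty")
  expect_error(reaction("r", c(A = 0)), "zero")
  expect_error(reaction("r", c(A = 1), lb = 5, ub = 1), "lower_bound")
  expect_error(metabolite("m", compartment = ""), "non-empty")
  m1 <- metabolite("A"); r1 <- reaction("r1", c(A = 1), 0, 10)
  expect_error(metabolic_model(rbind(m1, m1), list(r1), "r1"), "duplicate")
  expect_error(metabolic_model(m1, list(r1, r1), "r1"), "duplicate")
  expect_error(metabolic_model(m1, list(reaction("r2", c(B = -1))), "r2"),
               "undeclared")
  expect_error(metabolic_model(m1, list(r1), "nope"), "biomass")
})

test_that("gene rules parse to gene sets and malformed rules error", {
  expect_identical(gpr_genes("(g1 and g2) or g3"), c("g1", "g2", "g3"))
  expect_identical(gpr_genes(""), character())
  expect_identical(gpr_genes("g1 and g1"), "g1")
  expect_error(gpr_genes("g1 and"), "malformed")
  expect_error(gpr_genes("and g1"), "malformed")
  expect_error(gpr_genes("(g1 or g2"), "unbalanced")
  expect_error(gpr_genes("g1 g2"), "malformed|bad gene")
})

test_that("formula parsing handles multi-letter elements and counts", {
  f <- fluxscan:::parse_formula("C21H32N7O16P3S")
  expect_equal(f[["C"]], 21)
  expect_equal(f[["S"]], 1)
  expect_equal(f[["P"]], 3)
  expect_equal(fluxscan:::parse_formula("H")[["H"]], 1)
  expect_error(fluxscan:::parse_formula("c6h12"), "parse")
})

test_that("stoichiometric matrix reflects coefficients, stays stable under permutation", {
  t1 <- make_linear_toy()
  S <- stoichiometric_matrix(t1)
  expect_equal(dim(S), c(2L, 4L))      # boundary biomass row excluded
  expect_equal(S["A", "EX_glc"], 1)
  expect_equal(S["A", "R_bio"], -1)
  expect_equal(S["P", "R_p"], 1)
  # exchange columns carry exactly one entry
  expect_true(all(Matrix::colSums(S[, is_exchange(t1), drop = FALSE] != 0) == 1))
  # permuting reaction insertion order permutes columns identically
  perm <- c("R_p", "EX_p", "EX_glc", "R_bio")
  t1p <- metabolic_model(t1$metabolites, t1$reactions[perm],
                         biomass = "R_bio")
  Sp <- stoichiometric_matrix(t1p)
  expect_equal(as.matrix(Sp), as.matrix(S[, perm]))
  # full-row variant keeps the boundary metabolite
  expect_equal(nrow(stoichiometric_matrix(t1, include_boundary = TRUE)), 3L)
})

test_that("grafting appends exactly the module's columns, host entries unchanged", {
  host <- make_host_toy()
  S0 <- stoichiometric_matrix(host)
  mod <- build_ncm_module()
  g <- graft_module(host, mod, toy_host_mapping())
  S1 <- stoichiometric_matrix(g)
  expect_equal(ncol(S1), ncol(S0) + length(mod$reactions))
  common <- rownames(S0)
  expect_equal(as.matrix(S1[common, colnames(S0)]), as.matrix(S0))
})

test_that("validation reports dangling metabolites, imbalance, bad bounds and rules", {
  t1 <- make_linear_toy()
  expect_true(is_clean_report(validate_model(t1)))

  mets <- rbind(metabolite("glc", formula = "C6H12O6"),
                metabolite("lac", formula = "C3H6O3"),
                metabolite("unused"))
  m <- metabolic_model(mets,
                       list(reaction("conv", c(glc = -1, lac = 1), 0, 10),
                            reaction("bad", c(glc = 1), lb = 5, ub = 10),
                            reaction("EX_lac", c(lac = -1), 0, 10)),
                       biomass = "EX_lac")
  m$reactions$bad$lb <- 5; m$reactions$bad$ub <- 1   # planted violation
  m$reactions$conv$gpr <- "g1 and"                   # planted parse error
  rep <- validate_model(m)
  expect_identical(rep$dangling_metabolites, "unused")
  cimb <- rep$unbalanced_reactions[rep$unbalanced_reactions$element == "C", ]
  expect_identical(cimb$reaction_id, "conv")
  expect_equal(cimb$imbalance, -3)                   # C6 in, C3 out
  expect_identical(rep$bound_violations, "bad")
  expect_match(rep$gpr_parse_errors, "^conv")
  expect_false(rep$is_solvable)
})

test_that("medium setting caps the named uptake and closes other carbon sources", {
  mets <- rbind(metabolite("glc", formula = "C6H12O6"),
                metabolite("fru", formula = "C6H12O6"),
                metabolite("o2", formula = "O2"),
                metabolite("co2", formula = "CO2"),
                metabolite("B", compartment = "b", boundary = TRUE))
  rxns <- list(
    reaction("EX_glc", c(glc = -1), lb = -5, ub = 1000),
    reaction("EX_fru", c(fru = -1), lb = -5, ub = 1000),
    reaction("EX_o2", c(o2 = -1), lb = -20, ub = 1000),
    reaction("EX_co2", c(co2 = -1), lb = -1, ub = 1000),
    reaction("R_bio", c(glc = -1, fru = -0.1, B = 1), 0, 1000))
  m <- metabolic_model(mets, rxns, biomass = "R_bio")
  m2 <- set_medium(m, c(EX_glc = 10))
  expect_equal(m2$reactions$EX_glc$lb, -10)
  expect_equal(m2$reactions$EX_fru$lb, 0)        # alternative carbon closed
  expect_equal(m2$reactions$EX_o2$lb, -20)       # non-carbon untouched
  expect_equal(m2$reactions$EX_co2$lb, -1)       # inorganic whitelist
  # stoichiometry untouched, original unchanged
  expect_identical(m2$reactions$EX_glc$stoich, m$reactions$EX_glc$stoich)
  expect_equal(m$reactions$EX_fru$lb, -5)
  # starvation limit: closing all carbon kills growth
  m3 <- set_medium(m, c())
  expect_equal(maximize_flux(m3, "R_bio")$objective_value, 0, tolerance = 1e-9)
  # contract errors
  expect_error(set_medium(m, c(R_bio = 5)), "not exchange")
  expect_error(set_medium(m, c(EX_nope = 5)), "unknown")
  expect_error(set_medium(m, c(EX_glc = -3)), "non-negative")
})

test_that("import-form exchanges are capped on the upper bound", {
  t1 <- make_linear_toy()      # EX_glc written as -> A
  m2 <- set_medium(t1, c(EX_glc = 4))
  expect_equal(m2$reactions$EX_glc$ub, 4)
  expect_equal(maximize_flux(m2, "R_bio")$objective_value, 4, tolerance = 1e-9)
})
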