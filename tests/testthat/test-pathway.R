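test_that("the spinosyn module carries the four tagged rhamnose steps", {
  mod <- build_spinosad_module("branch")
  rham <- Filter(function(r) r$subsystem == "rhamnose branch", mod$reactions)
  expect_length(rham, 4L)
  expect_setequal(unlist(lapply(rham, function(r) gpr_genes(r$gpr))),
                  c("gtt", "gdh", "epi", "kre"))
  lump <- build_spinosad_module("lumped")
  rhaml <- Filter(function(r) r$subsystem == "rhamnose branch", lump$reactions)
  expect_length(rhaml, 1L)
  expect_setequal(gpr_genes(rhaml[[1]]$gpr), c("gtt", "gdh", "epi", "kre"))
})

test_that("grafting the spinosyn module onto the host enables production", {
  host <- make_host_toy()
  for (gran in c("branch", "lumped")) {
    mod <- build_spinosad_module(gran)
    g <- graft_module(host, mod, toy_host_mapping())
    expect_length(g$reactions, length(host$reactions) + length(mod$reactions))
    expect_gt(maximize_flux(g, "DM_spinosynA")$objective_value, 0)
    expect_gt(maximize_flux(g, "DM_spinosad")$objective_value, 0)
  }
})

test_that("spinosyn A needs all three branches: aglycone, rhamnose, forosamine", {
  host <- make_host_toy()
  g <- graft_module(host, build_spinosad_module("branch"), toy_host_mapping())
  for (blocked in c("R_agl_A", "R_rham_gtt", "R_rham_kre", "R_foro",
                    "R_psag_A")) {
    g2 <- apply_intervention(g, intervention_spec("knockout",
                                                  targets = blocked))
    expect_equal(maximize_flux(g2, "DM_spinosynA")$objective_value, 0,
                 tolerance = 1e-9, info = blocked)
  }
})

test_that("the NCM module releases no CO2, consumes no ATP, conserves carbon", {
  ncm <- build_ncm_module()
  species <- unique(unlist(lapply(ncm$reactions, function(r) names(r$stoich))))
  expect_false(any(grepl("^co2|^atp|^adp", species)))
  bal <- module_element_balance(ncm)
  expect_gt(nrow(bal), 0)
  expect_true(all(abs(bal$net) < 1e-9))
  carbon_in <- fluxscan:::parse_formula(ncm$species_formulas[["pyr_c"]])[["C"]]
  expect_equal(carbon_in, 3)  # C3 in, C3 through 3-oxopropanoate, C3 delivered
})

test_that("adding the NCM route never lowers, and can raise, a malonyl-CoA-limited maximum", {
  host <- make_host_toy()
  g <- graft_module(host, build_spinosad_module("lumped"), toy_host_mapping())
  before <- maximize_flux(g, "DM_spinosynA")$objective_value
  g2 <- graft_module(g, build_ncm_module(), toy_host_mapping())
  after <- maximize_flux(g2, "DM_spinosynA")$objective_value
  expect_gte(after, before - 1e-9)
  # with the carboxylase route capped, NCM relieves the malonyl-CoA limit
  capped <- set_bounds(g, "ACC", ub = 0.5)
  b2 <- maximize_flux(capped, "DM_spinosynA")$objective_value
  a2 <- maximize_flux(graft_module(capped, build_ncm_module(),
                                   toy_host_mapping()),
                      "DM_spinosynA")$objective_value
  expect_gt(a2, b2 + 1e-6)
})

test_that("graft bookkeeping: inactive module leaves growth alone, orphans error", {
  host <- make_host_toy()
  mod <- build_ncm_module()
  mu0 <- maximize_flux(host, "BIOMASS")$objective_value
  g <- graft_module(host, mod, toy_host_mapping())
  for (rid in names(mod$reactions)) g <- set_bounds(g, rid, lb = 0, ub = 0)
  expect_equal(maximize_flux(g, "BIOMASS")$objective_value, mu0,
               tolerance = 1e-9)
  mapping <- toy_host_mapping()
  mapping <- mapping[setdiff(names(mapping), "coa_c")]
  expect_error(graft_module(host, mod, mapping), "coa_c")
  bad <- toy_host_mapping(); bad[["coa_c"]] <- "no_such_met"
  expect_error(graft_module(host, mod, bad), "no_such_met")
})

test_that("interventions edit bounds as specified and amplify(1) is the identity", {
  tb <- make_branched_toy(toy_spec(seed = 4))$model
  ub0 <- tb$reactions$R_prec$ub
  amp <- apply_intervention(tb, intervention_spec("amplify",
                                                  targets = "R_prec",
                                                  factor = 2))
  expect_equal(amp$reactions$R_prec$ub, 2 * ub0)
  expect_gte(maximize_flux(amp, "EX_p")$objective_value,
             maximize_flux(tb, "EX_p")$objective_value - 1e-9)

  ko <- apply_intervention(tb, intervention_spec("knockout",
                                                 targets = "R_compete1"))
  expect_equal(ko$reactions$R_compete1$ub, 0)
  expect_gte(maximize_flux(ko, "EX_p")$objective_value,
             maximize_flux(tb, "EX_p")$objective_value - 1e-9)
  expect_lte(maximize_flux(ko, "R_bio")$objective_value,
             maximize_flux(tb, "R_bio")$objective_value + 1e-9)

  ident <- apply_intervention(tb, intervention_spec("amplify",
                                                    targets = "R_prec",
                                                    factor = 1))
  expect_identical(model_checksum(ident), model_checksum(tb))
  expect_error(apply_intervention(tb, intervention_spec("knockout",
                                                        targets = "nope")),
               "unknown")
})

test_that("maxima are monotone under grafting and knockouts on random toys", {
  for (seed in c(1, 6, 12)) {
    tb <- make_branched_toy(toy_spec(seed = seed))$model
    base_mu <- maximize_flux(tb, "R_bio")$objective_value
    base_p <- maximize_flux(tb, "EX_p")$objective_value
    g <- graft_module(tb, build_ncm_module(),
                      c(pyr_c = "PYR", coa_c = NA, nadp_c = NA, nadph_c = NA,
                        malcoa_c = "ACCOA", h_c = NA))
    expect_gte(maximize_flux(g, "R_bio")$objective_value, base_mu - 1e-9)
    expect_gte(maximize_flux(g, "EX_p")$objective_value, base_p - 1e-9)
    for (rid in c("R_compete1", "R_alt1")) {
      ko <- apply_intervention(tb, intervention_spec("knockout",
                                                     targets = rid))
      expect_lte(maximize_flux(ko, "EX_p")$objective_value, base_p + 1e-9)
    }
  }
})

test_that("scenario comparison reports base first, deltas and synergy", {
  # two independent caps: each edit alone is non-binding, jointly binding
  mets <- rbind(metabolite("A"), metabolite("M"), metabolite("R"),
                metabolite("P"), metabolite("B", compartment = "b",
                                            boundary = TRUE))
  m <- metabolic_model(
    mets,
    list(reaction("EX_a", c(A = 1), 0, 100),
         reaction("MK", c(A = -1, M = 1), 0, 5),     # malonyl-like cap
         reaction("RK", c(A = -1, R = 1), 0, 5),     # rhamnose-like cap
         reaction("ASM", c(M = -1, R = -1, P = 1), 0, 1000),
         reaction("EX_p", c(P = -1), 0, 1000),
         reaction("R_bio", c(A = -1, B = 1), 0, 1000)),
    biomass = "R_bio")
  ncm_like <- pathway_module(
    "bypass", list(reaction("MK2", c(A = -1, M = 1), 0, 100)),
    new_metabolites = metabolite("unused_c"), requires = c("A", "M"))
  scen <- list(
    amp_rham = list(intervention_spec("amplify", targets = "RK", factor = 2)),
    bypass = list(intervention_spec("add_module", module = ncm_like,
                                    mapping = c(A = "A", M = "M"))),
    both = list(intervention_spec("amplify", targets = "RK", factor = 2),
                intervention_spec("add_module", module = ncm_like,
                                  mapping = c(A = "A", M = "M"))),
    none = list())
  res <- compare_scenarios(m, scen, "EX_p", "EX_a",
                           biomass_floor_fraction = 0)
  expect_identical(res$scenario[1], "base")
  expect_equal(res$delta_vs_base[res$scenario == "base"], 0)
  expect_equal(res$delta_vs_base[res$scenario == "none"], 0, tolerance = 1e-9)
  d_amp <- res$delta_vs_base[res$scenario == "amp_rham"]
  d_byp <- res$delta_vs_base[res$scenario == "bypass"]
  d_both <- res$delta_vs_base[res$scenario == "both"]
  expect_equal(d_amp, 0, tolerance = 1e-9)
  expect_equal(d_byp, 0, tolerance = 1e-9)
  expect_gt(d_both, d_amp + d_byp + 1)    # synergy witness
  expect_true(all(res$yield_per_substrate >= 0, na.rm = TRUE))
})
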