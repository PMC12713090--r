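test_that("FBA on the linear toy hits the single bottleneck", {
  t1 <- make_linear_toy()
  mu <- maximize_flux(t1, "R_bio")
  expect_equal(mu$objective_value, 10, tolerance = 1e-9)
  expect_feasible(t1, mu)

  sol <- maximize_flux(t1, "EX_p", list(fixed_constraint("R_bio", 5)))
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)  # A = bio + prod

  inf <- maximize_flux(t1, "EX_p", list(fixed_constraint("R_bio", 11)))
  expect_identical(inf$status, "infeasible")
})

test_that("parsimonious FBA routes all flux through the short branch", {
  t3 <- make_redundant_toy()
  # plain FBA is degenerate: both routings reach the same objective
  byp <- apply_intervention(t3, intervention_spec("knockout",
                                                  targets = "R_direct"))
  expect_equal(maximize_flux(t3, "EX_p")$objective_value,
               maximize_flux(byp, "EX_p")$objective_value, tolerance = 1e-9)

  p <- pfba(t3, list(fixed_constraint("EX_p", 10)))
  expect_feasible(t3, p)
  # analytic enumeration: total |v| = 30 + 2t for detour flux t in [0, 10]
  t_grid <- seq(0, 10, by = 0.25)
  expect_equal(min(30 + 2 * t_grid), 30)
  expect_equal(p$objective_value, 30, tolerance = 1e-6)
  expect_equal(unname(p$fluxes[c("R_direct", "R_via1", "R_via2")]),
               c(10, 0, 0), tolerance = 1e-9)
  # blocking the short route forces the detour
  p2 <- pfba(byp, list(fixed_constraint("EX_p", 10)))
  expect_equal(unname(p2$fluxes[c("R_via1", "R_via2")]), c(10, 10),
               tolerance = 1e-9)
})

test_that("parsimonious FBA respects pins and never exceeds the plain solution's total flux", {
  t1 <- make_linear_toy()
  p <- pfba(t1, list(fixed_constraint("R_bio", 10)))
  expect_equal(p$fluxes[["EX_p"]], 0, tolerance = 1e-9)
  expect_equal(p$objective_value, 20, tolerance = 1e-6)   # uptake + growth

  for (seed in 1:5) {
    tb <- make_branched_toy(toy_spec(seed = seed))$model
    ct <- list(fixed_constraint("R_bio", 2))
    plain <- maximize_flux(tb, "EX_p", ct)
    pp <- pfba(tb, c(ct, list(fixed_constraint("EX_p",
                                               plain$objective_value))))
    expect_feasible(tb, pp)
    expect_lte(pp$objective_value, sum(abs(plain$fluxes)) + 1e-6)
    expect_equal(pp$fluxes[["R_bio"]], 2, tolerance = 1e-6)
    expect_equal(pp$fluxes[["EX_p"]], plain$objective_value, tolerance = 1e-6)
  }
})

test_that("a fully closed model admits only the zero flux vector", {
  t1 <- make_linear_toy()
  closed <- set_bounds(set_bounds(t1, "EX_glc", 0, 0), "EX_p", ub = 0)
  p <- pfba(closed)
  expect_equal(p$objective_value, 0, tolerance = 1e-9)
  expect_true(all(abs(p$fluxes) < 1e-9))
})

test_that("the production envelope traces the linear trade-off and is concave", {
  t1 <- make_linear_toy()
  fr <- seq(0.2, 0.8, by = 0.1)
  env <- production_envelope(t1, "R_bio", "EX_p", fr)
  expect_equal(env$target_max, 10 * (1 - fr), tolerance = 1e-9)
  expect_identical(unique(env$status), "optimal")
  env1 <- production_envelope(t1, "R_bio", "EX_p", 1.0)
  expect_equal(env1$target_max, 0, tolerance = 1e-9)
  # upper boundary concave in f on random branched toys (fine oracle grid)
  for (seed in c(2, 9)) {
    tb <- make_branched_toy(toy_spec(seed = seed))$model
    o <- oracle_scores(tb, scan_config("R_bio", "EX_p"), fine_step = 0.02)
    tm <- attr(o, "envelope")$target_max
    expect_true(all(diff(diff(tm)) < 1e-6))
  }
})

test_that("identical inputs give identical flux distributions", {
  tb <- make_branched_toy(toy_spec(seed = 11))$model
  a <- pfba(tb, list(fixed_constraint("R_bio", 1.5)))
  b <- pfba(tb, list(fixed_constraint("R_bio", 1.5)))
  expect_identical(a$fluxes, b$fluxes)
  expect_identical(a$objective_value, b$objective_value)
})

test_that("an unbounded objective is reported as unbounded, not an optimum", {
  mets <- rbind(metabolite("A"))
  m <- metabolic_model(
    mets, list(reaction("in", c(A = 1), 0, Inf),
               reaction("out", c(A = -1), 0, Inf)),
    biomass = "out")
  sol <- maximize_flux(m, "out")
  expect_identical(sol$status, "unbounded")
})
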