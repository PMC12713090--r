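test_that("scan config validates its grid", {
  expect_error(scan_config("b", "t", fractions = c(0.5, 0.3)), "")
  expect_error(scan_config("b", "t", fractions = c(0, 0.5)), "")
  expect_error(scan_config("b", "t", fractions = c(0.5, 1)), "")
  cfg <- scan_config("b", "t")
  expect_equal(cfg$fractions, seq(0.2, 0.8, by = 0.1))
})

test_that("the pure-growth control maximizes biomass with zero production", {
  t1 <- make_linear_toy()
  ctl <- run_control(t1, t1_config())
  expect_equal(ctl$objective_value, 10, tolerance = 1e-9)
  expect_equal(ctl$fluxes[["EX_p"]], 0, tolerance = 1e-9)
  # a model whose only sink is the product cannot grow; control is all-zero
  mets <- rbind(metabolite("A"), metabolite("P"),
                metabolite("B", compartment = "b", boundary = TRUE))
  m <- metabolic_model(mets,
                       list(reaction("EX_a", c(A = 1), 0, 10),
                            reaction("R_p", c(A = -1, P = 1), 0, 100),
                            reaction("EX_p", c(P = -1), 0, 100),
                            reaction("R_bio", c(A = -1, B = 1), 0, 0)),
                       biomass = "R_bio")
  ctl2 <- run_control(m, scan_config("R_bio", "EX_p"))
  expect_equal(ctl2$objective_value, 0, tolerance = 1e-9)
  expect_true(all(abs(ctl2$fluxes) < 1e-9))
  # infeasible medium propagates as a status
  bad <- set_bounds(t1, "EX_glc", lb = 20, ub = 30)  # forced uptake, no sink
  bad <- set_bounds(bad, "R_bio", ub = 5)
  bad <- set_bounds(bad, "R_p", ub = 5)
  expect_identical(run_control(bad, t1_config())$status, "infeasible")
})

test_that("the scan reproduces the linear toy's closed forms", {
  t1 <- make_linear_toy()
  sc <- run_scan(t1, t1_config())
  fr <- sc$config$fractions
  expect_equal(sc$max_biomass, 10, tolerance = 1e-9)
  expect_equal(unname(sc$target_max_per_level), 10 * (1 - fr),
               tolerance = 1e-9)
  m <- scan_matrix(sc)
  expect_equal(unname(m["EX_glc", paste0("f", format(fr))]),
               rep(10, length(fr)), tolerance = 1e-9)
  expect_equal(unname(m["R_bio", paste0("f", format(fr))]), 10 * fr,
               tolerance = 1e-9)
  # single-level scan
  sc1 <- run_scan(t1, t1_config(fractions = 0.5))
  expect_length(sc1$levels, 1L)
  expect_equal(sc1$levels[["0.5"]]$fluxes[["R_bio"]], 5, tolerance = 1e-9)
})

test_that("scores on the linear toy: uptake 1, biomass mean(fractions), product activated", {
  t1 <- make_linear_toy()
  s <- score_reactions(run_scan(t1, t1_config()))
  get <- function(col, rid) s[[col]][s$reaction_id == rid]
  expect_equal(get("score", "EX_glc"), 1, tolerance = 1e-12)
  expect_equal(get("score", "R_bio"), 0.5, tolerance = 1e-12)
  expect_true(get("activated", "R_p"))
  expect_equal(get("production_flux_mean", "R_p"), 5, tolerance = 1e-9)
  tt <- classify_targets(s, t1)
  expect_identical(tt$up$reaction_id, "R_p")
  expect_identical(tt$down$reaction_id, character(0))
  expect_setequal(tt$excluded$reaction_id, c("EX_glc", "R_bio", "EX_p"))
  expect_identical(
    tt$excluded$reason[tt$excluded$reaction_id == "R_bio"],
    "biomass reaction")
})

test_that("biomass score equals mean(fractions) on every instance (closed form)", {
  for (seed in c(2, 8, 21)) {
    tb <- make_branched_toy(toy_spec(seed = seed))$model
    for (fr in list(seq(0.2, 0.8, 0.1), c(0.3, 0.6), 0.25)) {
      s <- score_reactions(run_scan(tb, scan_config("R_bio", "EX_p",
                                                    fractions = fr)))
      expect_equal(s$score[s$reaction_id == "R_bio"], mean(fr),
                   tolerance = 1e-9)
    }
  }
})

test_that("a reaction with identical flux in control and levels scores exactly 1 and is neutral", {
  tb <- make_branched_toy(toy_spec(seed = 13))$model
  s <- score_reactions(run_scan(tb, scan_config("R_bio", "EX_p")))
  # the first core step carries the full uptake in every regime
  expect_equal(s$score[s$reaction_id == "R_core1"],
               s$score[s$reaction_id == "EX_glc"], tolerance = 1e-12)
  uptake_like <- s$reaction_id[!is.na(s$score) & abs(s$score - 1) < 1e-9]
  tt <- classify_targets(s, tb)
  for (rid in uptake_like) {
    expect_false(rid %in% c(tt$up$reaction_id, tt$down$reaction_id))
  }
})

test_that("classification is invariant to reaction order and uniform bound rescaling", {
  tb <- make_branched_toy(toy_spec(seed = 17))$model
  cfg <- scan_config("R_bio", "EX_p")
  tt <- classify_targets(score_reactions(run_scan(tb, cfg)), tb)

  perm <- rev(rxn_ids(tb))
  tbp <- metabolic_model(tb$metabolites, tb$reactions[perm],
                         biomass = "R_bio")
  ttp <- classify_targets(score_reactions(run_scan(tbp, cfg)), tbp)
  expect_setequal(ttp$up$reaction_id, tt$up$reaction_id)
  expect_setequal(ttp$down$reaction_id, tt$down$reaction_id)

  scaled <- tb
  for (rid in rxn_ids(scaled)) {
    r <- scaled$reactions[[rid]]
    scaled <- set_bounds(scaled, rid, lb = 2.5 * r$lb, ub = 2.5 * r$ub)
  }
  tts <- classify_targets(score_reactions(run_scan(scaled, cfg)), scaled)
  expect_identical(tts$up$reaction_id, tt$up$reaction_id)
  expect_identical(tts$down$reaction_id, tt$down$reaction_id)
  su <- score_reactions(run_scan(scaled, cfg))
  s0 <- score_reactions(run_scan(tb, cfg))
  expect_equal(su$score, s0$score, tolerance = 1e-9)
})

test_that("classification follows the score thresholds with the dead-band", {
  cfg <- scan_config("bio", "tgt", deadband = 0)
  mets <- rbind(metabolite("A"), metabolite("B", compartment = "b",
                                            boundary = TRUE))
  rx <- function(id) reaction(id, c(A = -1, B = 1), 0, 10, gpr = paste0("g", id))
  m <- metabolic_model(mets, list(reaction("up1", c(A = 1), 0, 40),
                                  rx("bio"), rx("tgt"), rx("r1"), rx("r2"),
                                  rx("r3"), rx("r4")),
                       biomass = "bio", objective = "bio")
  s <- fake_scores(data.frame(
    reaction_id = c("up1", "bio", "tgt", "r1", "r2", "r3", "r4"),
    score = c(1, 0.5, NA, 1.5, 1.0, 0.4, NA),
    activated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    control_flux = c(40, 10, 0, 1, 1, 1, 0),
    production_flux_mean = c(40, 5, 6, 1.5, 1, 0.4, 3),
    reason = c("scored", "scored", "activated", "scored", "scored",
               "scored", "activated")), cfg)
  tt <- classify_targets(s, m, cfg)
  expect_identical(tt$up$reaction_id, c("r4", "r1"))  # activated first
  expect_identical(tt$down$reaction_id, "r3")
  expect_true("r2" %in% tt$excluded$reaction_id)      # neutral at 1.0
  expect_identical(tt$excluded$reason[tt$excluded$reaction_id == "r2"],
                   "neutral")
  # all-inactive scan yields empty lists
  s2 <- s; s2$score <- 0; s2$activated <- FALSE; s2$reason <- "inactive"
  tt2 <- classify_targets(s2, m, cfg)
  expect_equal(nrow(tt2$up) + nrow(tt2$down), 0L)
})

test_that("gene scores take the extremal reaction score; ACTIVATED dominates", {
  mets <- rbind(metabolite("A"), metabolite("B", compartment = "b",
                                            boundary = TRUE))
  m <- metabolic_model(
    mets,
    list(reaction("in", c(A = 1), 0, 40),
         reaction("ra", c(A = -1, B = 1), 0, 10, gpr = "g1"),
         reaction("rb", c(A = -1, B = 1), 0, 10, gpr = "g1 and g2"),
         reaction("rc", c(A = -1, B = 1), 0, 10, gpr = "g3")),
    biomass = "ra")
  cfg <- scan_config("ra", "rc")
  s <- fake_scores(data.frame(
    reaction_id = c("in", "ra", "rb", "rc"),
    score = c(1, 1.5, 0.9, NA),
    activated = c(FALSE, FALSE, FALSE, TRUE),
    control_flux = c(10, 5, 5, 0),
    production_flux_mean = c(10, 7.5, 4.5, 2),
    reason = c("scored", "scored", "scored", "activated")), cfg)
  gs <- score_genes(m, s)
  g1 <- gs[gs$gene == "g1", ]
  expect_equal(g1$up_score, 1.5)           # max rule over {1.5, 0.9}
  expect_equal(g1$down_score, 0.9)         # min rule
  expect_identical(g1$reactions, "ra; rb")
  g2 <- gs[gs$gene == "g2", ]
  expect_equal(g2$up_score, 0.9)           # and-rule: inherits its reaction
  g3 <- gs[gs$gene == "g3", ]
  expect_true(g3$up_activated)             # activation dominates
  expect_false("g4" %in% gs$gene)
})

test_that("target-table export is deterministic and handles empty tables", {
  t1 <- make_linear_toy()
  tt <- classify_targets(score_reactions(run_scan(t1, t1_config())), t1)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_target_table(tt, f1)
  export_target_table(tt, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d <- utils::read.delim(f1, stringsAsFactors = FALSE)
  expect_equal(nrow(d), 1L)                # one up target, no down targets
  expect_identical(d$reaction_id, "R_p")
  expect_identical(d$score, "ACTIVATED")
  # empty table -> header only
  tt$up <- tt$up[0, ]; tt$down <- tt$down[0, ]
  export_target_table(tt, f1)
  expect_equal(nrow(utils::read.delim(f1)), 0L)
  expect_match(readLines(f1)[1], "^rank\treaction_id")
})

test_that("scoring refuses a scan without optimal levels", {
  t1 <- make_linear_toy()
  sc <- run_scan(t1, t1_config(fractions = 0.5))
  sc$levels[["0.5"]] <- flux_distribution(sc$control$fluxes * NA, NA_real_,
                                          "infeasible")
  expect_error(score_reactions(sc), "no optimal level")
})
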