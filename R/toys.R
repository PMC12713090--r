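#' Linear toy model ("T1")
#'
#' Four reactions, three metabolites: a single carbon uptake `EX_glc`
#' (`-> A`, uptake capped at 10), a biomass drain `R_bio` (`A -> BIO`,
#' `BIO` a boundary metabolite, the objective), a product branch `R_p`
#' (`A -> P`), and the product exchange `EX_p` (`P ->`). Every flux fact
#' about this fixture has a closed form: max biomass is 10 and the
#' production envelope is `10 (1 - f)`.
#'
#' The same fixture is frozen at
#' `system.file("extdata", "toy_linear.json", package = "fluxscan")`.
#'
#' @return A `gem_model`.
#' @export
make_linear_toy <- function() {
  mets <- rbind(
    metabolite("A", name = "carbon pool", formula = "C6H12O6"),
    metabolite("P", name = "product", formula = "C6H12O6"),
    metabolite("BIO", name = "biomass", compartment = "b", boundary = TRUE))
  rxns <- list(
    reaction("EX_glc", c(A = 1), lb = 0, ub = 10, name = "carbon uptake"),
    reaction("R_bio", c(A = -1, BIO = 1), lb = 0, ub = 1000, name = "growth"),
    reaction("R_p", c(A = -1, P = 1), lb = 0, ub = 1000, name = "product branch"),
    reaction("EX_p", c(P = -1), lb = 0, ub = 1000, name = "product exchange"))
  metabolic_model(mets, rxns, biomass = "R_bio", id = "toy_linear")
}

#' Redundant-route toy model ("T3")
#'
#' Two parallel routes from A to P: a direct one-step reaction and a
#' two-step detour via X. Plain FBA is degenerate between the routings;
#' parsimonious FBA must put all flux on the one-step route. With the
#' product exchange pinned at `q`, total absolute flux is `3q + 2t` where
#' `t` is the detour flux, minimized at `t = 0`.
#'
#' @return A `gem_model`.
#' @export
make_redundant_toy <- function() {
  mets <- rbind(
    metabolite("A", formula = "C6H12O6"),
    metabolite("X", formula = "C6H12O6"),
    metabolite("P", formula = "C6H12O6"))
  rxns <- list(
    reaction("EX_a", c(A = 1), lb = 0, ub = 1000),
    reaction("R_direct", c(A = -1, P = 1), lb = 0, ub = 1000),
    reaction("R_via1", c(A = -1, X = 1), lb = 0, ub = 1000),
    reaction("R_via2", c(X = -1, P = 1), lb = 0, ub = 1000),
    reaction("EX_p", c(P = -1), lb = 0, ub = 1000))
  metabolic_model(mets, rxns, biomass = "EX_p", id = "toy_redundant")
}

#' Specification for the branched toy family ("T2")
#'
#' @param n_core_reactions Number of reactions in the linear core backbone
#'   (uptake, glucose-to-G6P chain, glycolysis, precursor steps); >= 5.
#' @param n_competing_branches Number of growth-only branches draining the
#'   capped precursor pool.
#' @param bottleneck_position `"precursor"` plants a capped upper bound on
#'   the precursor-supply reaction; `"none"` leaves it open.
#' @param seed Integer; the generator is a pure function of the spec.
#' @param bound_range Range (lo, hi) for log-uniform background bounds;
#'   chosen above any attainable flux so only the planted cap binds.
#' @param bottleneck_ub Optional explicit cap override (testing aid).
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(n_core_reactions = 5, n_competing_branches = 1,
                     bottleneck_position = c("precursor", "none"),
                     seed = 1, bound_range = c(25, 250),
                     bottleneck_ub = NULL) {
  bottleneck_position <- match.arg(bottleneck_position)
  stopifnot(n_core_reactions >= 5, n_competing_branches >= 1,
            length(bound_range) == 2, all(bound_range > 0),
            bound_range[1] < bound_range[2])
  structure(list(n_core_reactions = n_core_reactions,
                 n_competing_branches = n_competing_branches,
                 bottleneck_position = bottleneck_position,
                 seed = as.integer(seed), bound_range = bound_range,
                 bottleneck_ub = bottleneck_ub),
            class = "toy_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Branched toy family with planted ground truth ("T2")
#'
#' Emulates the structure the scan assumes: a single glucose uptake feeding
#' a core chain (glucose -> G6P -> pyruvate -> acetyl-CoA-like pool), a
#' redundant two-step bypass of the first core step (exercising pFBA), a
#' sugar branch, a capped precursor-supply reaction (`R_prec`, the planted
#' bottleneck) whose pool feeds both growth-only competing branches
#' (`R_compete_*`, planted attenuation targets) and a two-step product
#' module (`R_agl` + `R_asm`, acyl-like and sugar-like precursors merging
#' into the product P).
#'
#' The cap on `R_prec` is drawn so that (i) it does not limit growth,
#' (ii) it exceeds the pure-growth demand by at least 10% (so its score is
#' classifiably > 1), and (iii) it binds production at every enforced
#' growth level. Planted expectations: `R_prec`, `R_agl`, `R_asm` up;
#' every `R_compete_*` down.
#'
#' @param spec A [toy_spec()].
#' @return List with elements `model` (a `gem_model`) and `truth` (a list
#'   with `expected_up`, `expected_down`, `rationale`).
#' @export
make_branched_toy <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  if (!is.null(spec$bottleneck_ub) && spec$bottleneck_ub <= 0)
    stop("degenerate toy_spec: bottleneck cap ", spec$bottleneck_ub,
         " admits no product route")
  with_seed(spec$seed, {
    nc <- spec$n_competing_branches
    k <- spec$n_core_reactions - 4L          # chain steps glucose -> G6P
    uptake <- 10
    alpha <- stats::runif(1, 0.8, 1.5)       # sugar per biomass
    beta <- stats::runif(1, 0.8, 1.5)        # acetyl-CoA per biomass
    gam <- stats::runif(nc, 0.2, 0.35) / nc  # precursor per biomass, per branch
    gtot <- sum(gam)
    mu_max <- uptake / (alpha + (beta + gtot) / 2)
    c0 <- gtot * mu_max                      # pure-growth precursor demand
    draw <- function(n = 1) runif_log(n, spec$bound_range[1], spec$bound_range[2])

    chain_ids <- sprintf("C%d", seq_len(max(k - 1L, 0L)))
    mets <- rbind(
      metabolite("GLC", formula = "C6H12O6"),
      if (length(chain_ids))
        do.call(rbind, lapply(chain_ids, metabolite)),
      metabolite("XALT"), metabolite("G6P"), metabolite("PYR"),
      metabolite("ACCOA"), metabolite("PREC"), metabolite("SUG"),
      metabolite("AGL"),
      do.call(rbind, lapply(seq_len(nc), function(i) metabolite(sprintf("FA%d", i)))),
      metabolite("P", formula = "C20H30O6"),
      metabolite("BIO", compartment = "b", boundary = TRUE))

    chain_nodes <- c("GLC", chain_ids, "G6P")
    core <- lapply(seq_len(k), function(i) {
      reaction(sprintf("R_core%d", i),
               stats::setNames(c(-1, 1), chain_nodes[c(i, i + 1L)]),
               lb = 0, ub = draw(), subsystem = "core")
    })
    bio_st <- c(SUG = -alpha, ACCOA = -beta,
                stats::setNames(-gam, sprintf("FA%d", seq_len(nc))), BIO = 1)
    bottleneck <- spec$bottleneck_ub %||% switch(
      spec$bottleneck_position,
      precursor = runif_log(1, 1.1 * c0, 0.76 * c0 + 0.95),
      none = draw())
    rxns <- c(
      list(reaction("EX_glc", c(GLC = 1), lb = 0, ub = uptake)),
      core,
      list(
        reaction("R_alt1", c(GLC = -1, XALT = 1), lb = 0, ub = draw(),
                 subsystem = "bypass"),
        reaction("R_alt2", stats::setNames(c(-1, 1), c("XALT", chain_nodes[2L])),
                 lb = 0, ub = draw(), subsystem = "bypass"),
        reaction("R_glyc", c(G6P = -1, PYR = 2), lb = 0, ub = draw(),
                 gpr = "pyk1"),
        reaction("R_pdh", c(PYR = -1, ACCOA = 1), lb = 0, ub = draw(),
                 gpr = "pdhA and pdhB"),
        reaction("R_sug", c(G6P = -1, SUG = 1), lb = 0, ub = draw(),
                 gpr = "sugT"),
        reaction("R_prec", c(ACCOA = -1, PREC = 1), lb = 0, ub = bottleneck,
                 gpr = "pccB", subsystem = "precursor supply")),
      lapply(seq_len(nc), function(i)
        reaction(sprintf("R_compete%d", i),
                 stats::setNames(c(-1, 1), c("PREC", sprintf("FA%d", i))),
                 lb = 0, ub = draw(), gpr = sprintf("fab%d", i),
                 subsystem = "competing branch")),
      list(
        reaction("R_bio", bio_st, lb = 0, ub = draw(), name = "biomass"),
        reaction("R_agl", c(ACCOA = -1, PREC = -1, AGL = 1), lb = 0, ub = draw(),
                 gpr = "pksA and pksB", subsystem = "product module"),
        reaction("R_asm", c(AGL = -1, SUG = -1, P = 1), lb = 0, ub = draw(),
                 gpr = "gtA", subsystem = "product module"),
        reaction("EX_p", c(P = -1), lb = 0, ub = 1000)))

    model <- metabolic_model(mets, rxns, biomass = "R_bio",
                             id = sprintf("toy_branched_seed%d", spec$seed))
    truth <- list(
      expected_up = c(if (spec$bottleneck_position == "precursor") "R_prec",
                      "R_agl", "R_asm"),
      expected_down = sprintf("R_compete%d", seq_len(nc)),
      rationale = c(
        R_prec = "capped precursor supply; production presses it above growth demand",
        R_agl = "product module, zero flux under pure growth",
        R_asm = "product module, zero flux under pure growth",
        stats::setNames(rep("growth-only precursor drain, shrinks under production",
                            nc), sprintf("R_compete%d", seq_len(nc)))))
    list(model = model, truth = truth)
  })
}

#' Deterministic checksum of a model
#'
#' MD5 over the canonical JSON serialization; equal specs give equal
#' checksums.
#'
#' @param model A `gem_model`.
#' @return Character scalar.
#' @export
model_checksum <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_model(model, tf, "json")
  unname(tools::md5sum(tf))
}
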