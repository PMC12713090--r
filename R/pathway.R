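#' Graftable pathway module
#'
#' A self-contained reaction set ready to merge into a host model:
#' reactions, newly introduced metabolites, the currency species that must
#' be resolved to host metabolites at graft time, a formula table used for
#' structural (elemental) accounting, and per-reaction provenance notes.
#'
#' @param name Module name.
#' @param reactions List of [reaction()]s.
#' @param new_metabolites Metabolite data frame (the species the module
#'   introduces).
#' @param requires Character vector of species ids that the graft mapping
#'   must resolve to host metabolites (or explicitly drop).
#' @param species_formulas Named character vector of elemental formulas for
#'   structural accounting (may cover both new and required species).
#' @param notes Named character vector, reaction id -> provenance note.
#' @return A list of class `pathway_module`.
#' @export
pathway_module <- function(name, reactions, new_metabolites, requires,
                           species_formulas = character(), notes = character()) {
  rids <- vapply(reactions, function(r) r$id, "")
  names(reactions) <- rids
  if (anyDuplicated(rids)) stop("duplicate reaction ids in module ", name)
  structure(list(name = name, reactions = reactions,
                 new_metabolites = new_metabolites, requires = requires,
                 species_formulas = species_formulas, notes = notes),
            class = "pathway_module")
}

#' @export
print.pathway_module <- function(x, ...) {
  cat("<pathway_module> ", x$name, ": ", length(x$reactions), " reactions, ",
      nrow(x$new_metabolites), " new metabolites, ",
      length(x$requires), " host-mapped species\n", sep = "")
  invisible(x)
}

#' The spinosyn biosynthetic module
#'
#' Encodes the route from central-carbon precursors to spinosyns A and D:
#' (i) polyketide aglycone assembly from an acetyl-CoA starter (spinosyn A)
#' or propionyl-CoA starter (spinosyn D, carrying the extra 6-position
#' methyl) plus malonyl-CoA and methylmalonyl-CoA extenders; (ii) the
#' TDP-L-rhamnose branch (glucose-1-phosphate -> TDP-glucose ->
#' 4,6-dehydration -> 3,5-epimerization -> 4-keto reduction; genes gtt,
#' gdh, epi, kre); (iii) a lumped TDP-D-forosamine branch; (iv) attachment
#' and tailoring: pseudoaglycone = aglycone + rhamnose, spinosyn =
#' O-methylated pseudoaglycone + forosamine; (v) demand reactions for
#' spinosyn A, spinosyn D, and the 0.85:0.15 spinosad blend.
#'
#' Cofactor stoichiometry (NADPH, SAM, TDP counts) is a documented,
#' overridable default: the pathway topology fixes which branches are
#' obligatory, not the cofactant coefficients, and every choice is carried
#' in the module notes.
#'
#' @param granularity `"branch"` keeps the four rhamnose steps as separate
#'   gene-tagged reactions; `"lumped"` collapses each branch to one
#'   reaction.
#' @param aglycone_nadph NADPH consumed per aglycone (reductive PKS
#'   tailoring; documented default 6).
#' @return A [pathway_module()]. The default scan target is the spinosyn A
#'   demand `DM_spinosynA`.
#' @export
build_spinosad_module <- function(granularity = c("branch", "lumped"),
                                  aglycone_nadph = 6) {
  granularity <- match.arg(granularity)
  new_mets <- rbind(
    metabolite("dtdpglc_c", "dTDP-glucose"),
    if (granularity == "branch") rbind(
      metabolite("dtdp4o6d_c", "dTDP-4-oxo-6-deoxyglucose"),
      metabolite("dtdpdhrmn_c", "dTDP-4-dehydro-L-rhamnose")),
    metabolite("dtdprmn_c", "dTDP-L-rhamnose"),
    metabolite("dtdpfor_c", "dTDP-D-forosamine"),
    metabolite("aglA_c", "spinosyn A aglycone"),
    metabolite("aglD_c", "spinosyn D aglycone"),
    metabolite("psagA_c", "spinosyn A pseudoaglycone"),
    metabolite("psagD_c", "spinosyn D pseudoaglycone"),
    metabolite("spinosynA_c", "spinosyn A", formula = "C41H65NO10"),
    metabolite("spinosynD_c", "spinosyn D", formula = "C42H67NO10"))
  requires <- c("accoa_c", "ppcoa_c", "malcoa_c", "mmcoa_c", "coa_c",
                "g1p_c", "dttp_c", "tdp_c", "ppi_c", "nadph_c", "nadp_c",
                "amet_c", "ahcys_c", "nh4_c", "h2o_c", "h_c")
  nph <- aglycone_nadph
  agl_note <- paste("documented default: 1 starter + 7 malonyl-CoA +",
                    "2 methylmalonyl-CoA extenders,", nph,
                    "NADPH for reductive tailoring; CoA released per extender")
  rham_steps <- if (granularity == "branch") list(
    reaction("R_rham_gtt", c(g1p_c = -1, dttp_c = -1, h_c = -1,
                             dtdpglc_c = 1, ppi_c = 1),
             lb = 0, ub = 1000, gpr = "gtt",
             name = "glucose-1-phosphate thymidylyltransferase",
             subsystem = "rhamnose branch"),
    reaction("R_rham_gdh", c(dtdpglc_c = -1, dtdp4o6d_c = 1, h2o_c = 1),
             lb = 0, ub = 1000, gpr = "gdh",
             name = "dTDP-glucose 4,6-dehydratase",
             subsystem = "rhamnose branch"),
    reaction("R_rham_epi", c(dtdp4o6d_c = -1, dtdpdhrmn_c = 1),
             lb = 0, ub = 1000, gpr = "epi",
             name = "dTDP-4-dehydrorhamnose 3,5-epimerase",
             subsystem = "rhamnose branch"),
    reaction("R_rham_kre", c(dtdpdhrmn_c = -1, nadph_c = -1, h_c = -1,
                             dtdprmn_c = 1, nadp_c = 1),
             lb = 0, ub = 1000, gpr = "kre",
             name = "dTDP-4-dehydrorhamnose reductase",
             subsystem = "rhamnose branch")
  ) else list(
    reaction("R_rham_lumped", c(g1p_c = -1, dttp_c = -1, nadph_c = -1,
                                h_c = -2, dtdprmn_c = 1, ppi_c = 1,
                                nadp_c = 1, h2o_c = 1),
             lb = 0, ub = 1000, gpr = "gtt and gdh and epi and kre",
             name = "TDP-L-rhamnose branch (lumped)",
             subsystem = "rhamnose branch"))
  rxns <- c(list(
    reaction("R_agl_A", c(accoa_c = -1, malcoa_c = -7, mmcoa_c = -2,
                          nadph_c = -nph, aglA_c = 1, coa_c = 10,
                          nadp_c = nph),
             lb = 0, ub = 1000,
             gpr = "spnA and spnB and spnC and spnD and spnE",
             name = "spinosyn A aglycone assembly (PKS, lumped)",
             subsystem = "aglycone"),
    reaction("R_agl_D", c(ppcoa_c = -1, malcoa_c = -7, mmcoa_c = -2,
                          nadph_c = -nph, aglD_c = 1, coa_c = 10,
                          nadp_c = nph),
             lb = 0, ub = 1000,
             gpr = "spnA and spnB and spnC and spnD and spnE",
             name = "spinosyn D aglycone assembly (PKS, lumped)",
             subsystem = "aglycone")),
    rham_steps,
    list(
      reaction("R_foro", c(g1p_c = -1, dttp_c = -1, amet_c = -2, nh4_c = -1,
                           nadph_c = -2, dtdpfor_c = 1, ppi_c = 1,
                           ahcys_c = 2, nadp_c = 2, h2o_c = 2),
               lb = 0, ub = 1000,
               gpr = "spnO and spnN and spnQ and spnR and spnS",
               name = "TDP-D-forosamine branch (lumped)",
               subsystem = "forosamine branch"),
      reaction("R_psag_A", c(aglA_c = -1, dtdprmn_c = -1, psagA_c = 1,
                             tdp_c = 1),
               lb = 0, ub = 1000, gpr = "spnG",
               name = "rhamnosylation of spinosyn A aglycone",
               subsystem = "attachment"),
      reaction("R_psag_D", c(aglD_c = -1, dtdprmn_c = -1, psagD_c = 1,
                             tdp_c = 1),
               lb = 0, ub = 1000, gpr = "spnG",
               name = "rhamnosylation of spinosyn D aglycone",
               subsystem = "attachment"),
      reaction("R_spnA", c(psagA_c = -1, amet_c = -3, dtdpfor_c = -1,
                           spinosynA_c = 1, ahcys_c = 3, tdp_c = 1),
               lb = 0, ub = 1000, gpr = "spnH and spnI and spnK and spnP",
               name = "tri-O-methylation and forosaminylation (A)",
               subsystem = "tailoring"),
      reaction("R_spnD", c(psagD_c = -1, amet_c = -3, dtdpfor_c = -1,
                           spinosynD_c = 1, ahcys_c = 3, tdp_c = 1),
               lb = 0, ub = 1000, gpr = "spnH and spnI and spnK and spnP",
               name = "tri-O-methylation and forosaminylation (D)",
               subsystem = "tailoring"),
      reaction("DM_spinosynA", c(spinosynA_c = -1), lb = 0, ub = 1000,
               name = "spinosyn A demand"),
      reaction("DM_spinosynD", c(spinosynD_c = -1), lb = 0, ub = 1000,
               name = "spinosyn D demand"),
      reaction("DM_spinosad", c(spinosynA_c = -0.85, spinosynD_c = -0.15),
               lb = 0, ub = 1000,
               name = "spinosad blend demand (0.85 A : 0.15 D)")))
  notes <- c(R_agl_A = agl_note, R_agl_D = paste(agl_note, "; propionyl start"),
             R_foro = "lumped: TDP-sugar, transamination from ammonium, 2 SAM N-methylations, 2 NADPH deoxygenations",
             DM_spinosad = "congener blend, A:D = 0.85:0.15")
  pathway_module("spinosad", rxns, new_mets, requires, notes = notes)
}

#' The non-carboxylative malonyl-CoA (NCM) module
#'
#' Two reactions converting pyruvate to malonyl-CoA via 3-oxopropanoate
#' (malonate semialdehyde): `BauA` (pyruvate -> 3-oxopropanoate; at this
#' level of lumping elementally an isomerization, both species C3H3O3) and
#' `MCR-C` (3-oxopropanoate + CoA + NADP+ -> malonyl-CoA + NADPH + H+,
#' written oxidatively with NADP+ as the documented, overridable electron
#' acceptor). The route releases no CO2, loses no carbon, and consumes no
#' ATP, in contrast to the acetyl-CoA carboxylase route.
#'
#' @return A [pathway_module()].
#' @export
build_ncm_module <- function() {
  new_mets <- rbind(
    metabolite("msa_c", "3-oxopropanoate (malonate semialdehyde)",
               formula = "C3H3O3", charge = -1L))
  requires <- c("pyr_c", "coa_c", "nadp_c", "nadph_c", "malcoa_c", "h_c")
  rxns <- list(
    reaction("R_ncm_bauA", c(pyr_c = -1, msa_c = 1), lb = 0, ub = 1000,
             gpr = "BauA", name = "pyruvate -> 3-oxopropanoate",
             subsystem = "NCM"),
    reaction("R_ncm_mcrC", c(msa_c = -1, coa_c = -1, nadp_c = -1,
                             malcoa_c = 1, nadph_c = 1, h_c = 1),
             lb = 0, ub = 1000, gpr = "MCR-C",
             name = "3-oxopropanoate + CoA -> malonyl-CoA",
             subsystem = "NCM"))
  formulas <- c(pyr_c = "C3H3O3", msa_c = "C3H3O3",
                coa_c = "C21H32N7O16P3S", malcoa_c = "C24H33N7O19P3S",
                nadp_c = "C21H25N7O17P3", nadph_c = "C21H26N7O17P3",
                h_c = "H")
  notes <- c(R_ncm_bauA = "C3 -> C3, no CO2 release, no ATP; cofactor-free at this lumping",
             R_ncm_mcrC = "oxidative direction; NADP+ as acceptor (documented default)")
  pathway_module("NCM", rxns, new_mets, requires,
                 species_formulas = formulas, notes = notes)
}

#' Elemental balance of a module's reactions
#'
#' Uses the module's own formula table (falling back to formulas on its new
#' metabolites); reactions whose species are not fully covered are skipped.
#'
#' @param module A [pathway_module()].
#' @return Data frame `reaction_id`, `element`, `net` (0 = balanced), one
#'   row per element of each checkable reaction.
#' @export
module_element_balance <- function(module) {
  fmap <- module$species_formulas
  nm <- module$new_metabolites
  for (i in seq_len(nrow(nm))) {
    if (!is.na(nm$formula[i]) && !nm$id[i] %in% names(fmap))
      fmap[nm$id[i]] <- nm$formula[i]
  }
  out <- data.frame(reaction_id = character(), element = character(),
                    net = numeric(), stringsAsFactors = FALSE)
  for (r in module$reactions) {
    if (!all(names(r$stoich) %in% names(fmap))) next
    counts <- list()
    for (k in seq_along(r$stoich)) {
      f <- parse_formula(fmap[[names(r$stoich)[k]]])
      for (el in names(f))
        counts[[el]] <- (counts[[el]] %||% 0) + r$stoich[[k]] * f[[el]]
    }
    for (el in names(counts))
      out <- rbind(out, data.frame(reaction_id = r$id, element = el,
                                   net = counts[[el]], stringsAsFactors = FALSE))
  }
  out
}

#' Graft a pathway module onto a host model
#'
#' Module reactions are appended; currency species listed in
#' `module$requires` are renamed to host metabolites through `mapping`.
#' A mapping value of `NA` drops the species from the grafted stoichiometry
#' (treated as freely buffered by the host — every such choice should be a
#' deliberate, documented one). Species in `module$new_metabolites` are
#' added to the model. Host reactions and bounds are untouched.
#'
#' @param model Host `gem_model`.
#' @param module A [pathway_module()].
#' @param mapping Named character vector, module species id -> host
#'   metabolite id (or `NA` to drop). Must cover every id in
#'   `module$requires`. See [bigg_mapping()] and [toy_host_mapping()].
#' @return The extended `gem_model`.
#' @export
graft_module <- function(model, module, mapping) {
  orphans <- setdiff(module$requires, names(mapping))
  if (length(orphans))
    stop("graft mapping does not resolve module species: ",
         paste(orphans, collapse = ", "))
  bad_host <- stats::na.omit(setdiff(mapping, met_ids(model)))
  if (length(bad_host))
    stop("mapping points at unknown host metabolite(s): ",
         paste(bad_host, collapse = ", "))
  clash <- intersect(module$new_metabolites$id, met_ids(model))
  if (length(clash))
    stop("module metabolite id(s) collide with host: ",
         paste(clash, collapse = ", "))
  rclash <- intersect(names(module$reactions), rxn_ids(model))
  if (length(rclash))
    stop("module reaction id(s) collide with host: ",
         paste(rclash, collapse = ", "))

  new_ids <- module$new_metabolites$id
  remap <- function(st) {
    ids <- names(st)
    keep <- logical(length(st))
    out_ids <- character(length(st))
    for (k in seq_along(st)) {
      id <- ids[k]
      if (id %in% new_ids) { keep[k] <- TRUE; out_ids[k] <- id }
      else if (id %in% names(mapping)) {
        if (is.na(mapping[[id]])) keep[k] <- FALSE
        else { keep[k] <- TRUE; out_ids[k] <- mapping[[id]] }
      } else stop("module species '", id, "' neither new nor mapped")
    }
    st <- st[keep]; ids <- out_ids[keep]
    agg <- tapply(st, ids, sum)
    agg <- agg[abs(agg) > 1e-12]
    stats::setNames(as.numeric(agg), names(agg))
  }
  new_rxns <- lapply(module$reactions, function(r) {
    st <- remap(r$stoich)
    if (length(st) == 0L)
      stop("module reaction '", r$id, "' maps to empty stoichiometry")
    reaction(r$id, st, lb = r$lb, ub = r$ub, name = r$name, gpr = r$gpr,
             subsystem = r$subsystem)
  })
  metabolic_model(rbind(model$metabolites, module$new_metabolites),
                  c(model$reactions, new_rxns),
                  biomass = model$biomass_reaction_id,
                  objective = model$objective_reaction_id,
                  id = paste0(model$id, "+", module$name))
}

#' Identity mapping for BiGG-style hosts
#'
#' For hosts whose metabolites already use BiGG-style ids, every module
#' currency species maps to the host metabolite of the same id.
#'
#' @param module A [pathway_module()].
#' @return Named character vector usable as a [graft_module()] mapping.
#' @export
bigg_mapping <- function(module) {
  stats::setNames(module$requires, module$requires)
}

#' An intervention on a model
#'
#' @param kind `"amplify"` (multiply both bounds of the target reactions by
#'   `factor`, the in-silico image of extra gene copies / stronger
#'   promoters), `"knockout"` (zero both bounds), `"add_module"` (graft
#'   `module` with `mapping`), or `"enable_degradation"` (open previously
#'   closed degradation reactions to `[0, factor]`, the static image of the
#'   dynamic TAG-degradation strategy).
#' @param targets Reaction ids (for amplify / knockout /
#'   enable_degradation).
#' @param factor Positive number; bound multiplier (amplify) or opened
#'   upper bound (enable_degradation, default 1000).
#' @param module,mapping For `add_module`.
#' @return A list of class `intervention_spec`.
#' @export
intervention_spec <- function(kind = c("amplify", "add_module", "knockout",
                                       "enable_degradation"),
                              targets = NULL, factor = 1, module = NULL,
                              mapping = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(factor), factor > 0)
  if (kind == "add_module" && is.null(module))
    stop("add_module intervention needs a module")
  if (kind != "add_module" && is.null(targets))
    stop(kind, " intervention needs target reaction ids")
  structure(list(kind = kind, targets = targets, factor = factor,
                 module = module, mapping = mapping),
            class = "intervention_spec")
}

#' Apply an intervention to a model
#'
#' @param model A `gem_model`.
#' @param spec An [intervention_spec()].
#' @return The edited copy; the input model is unchanged.
#' @export
apply_intervention <- function(model, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (spec$kind == "add_module")
    return(graft_module(model, spec$module, spec$mapping))
  unknown <- setdiff(spec$targets, rxn_ids(model))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  for (rid in spec$targets) {
    r <- model$reactions[[rid]]
    model <- switch(spec$kind,
      amplify = set_bounds(model, rid, lb = r$lb * spec$factor,
                           ub = r$ub * spec$factor),
      knockout = set_bounds(model, rid, lb = 0, ub = 0),
      enable_degradation = set_bounds(model, rid, lb = 0,
                                      ub = if (identical(spec$factor, 1)) 1000
                                           else spec$factor))
  }
  model
}

#' Compare intervention scenarios
#'
#' Each scenario (a list of interventions) is applied to the base model and
#' evaluated by maximizing the target flux while requiring biomass to stay
#' at or above `biomass_floor_fraction` of that scenario's own maximal
#' growth. The unmodified base is always evaluated and reported first.
#'
#' @param model Base `gem_model`.
#' @param scenarios Named list; each element a list of
#'   [intervention_spec()]s (possibly empty).
#' @param target_reaction_id Production target.
#' @param substrate_exchange_id Substrate uptake exchange, for yield.
#' @param biomass_floor_fraction In `[0, 1)`; default 0.1.
#' @return Data frame of class `scenario_results`: one row per scenario
#'   (base first) with `max_target_flux`, `yield_per_substrate`,
#'   `delta_vs_base`, `status`. Infeasible scenarios are flagged, not
#'   dropped.
#' @export
compare_scenarios <- function(model, scenarios, target_reaction_id,
                              substrate_exchange_id,
                              biomass_floor_fraction = 0.1) {
  stopifnot(biomass_floor_fraction >= 0, biomass_floor_fraction < 1)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    stop("scenarios must be named")
  all_scen <- c(list(base = list()), scenarios)
  rows <- list()
  base_max <- NA_real_
  for (nm in names(all_scen)) {
    m2 <- model
    ok <- TRUE
    for (sp in all_scen[[nm]]) {
      m2 <- tryCatch(apply_intervention(m2, sp), error = function(e) {
        ok <<- FALSE; m2
      })
      if (!ok) break
    }
    row <- data.frame(scenario = nm, status = "error",
                      max_target_flux = NA_real_, substrate_uptake = NA_real_,
                      yield_per_substrate = NA_real_, delta_vs_base = NA_real_,
                      stringsAsFactors = FALSE)
    if (ok) {
      mu <- maximize_flux(m2, m2$biomass_reaction_id)
      if (mu$status != "optimal") {
        row$status <- mu$status
      } else {
        floor_v <- biomass_floor_fraction * mu$objective_value
        m3 <- set_bounds(m2, m2$biomass_reaction_id,
                         lb = max(m2$reactions[[m2$biomass_reaction_id]]$lb,
                                  floor_v))
        sol <- maximize_flux(m3, target_reaction_id)
        row$status <- sol$status
        if (sol$status == "optimal") {
          row$max_target_flux <- sol$objective_value
          upt <- abs(sol$fluxes[[substrate_exchange_id]])
          row$substrate_uptake <- upt
          row$yield_per_substrate <- if (upt > 1e-12)
            sol$objective_value / upt else 0
        }
      }
    }
    if (nm == "base" && row$status == "optimal") base_max <- row$max_target_flux
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  out$delta_vs_base <- out$max_target_flux - base_max
  rownames(out) <- NULL
  class(out) <- c("scenario_results", class(out))
  out
}
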