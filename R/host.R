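#' Desk-scale actinomycete-like host model ("H1")
#'
#' A small host emulating the features the grafted chemistry needs: a
#' single glucose uptake, ATP/NADPH cofactor cycling (conserved adenylate
#' and NADP pools), glucose-1-phosphate and short-chain acyl-CoA pools
#' (acetyl-, malonyl-, methylmalonyl-, propionyl-CoA), an ACC-style
#' ATP-consuming malonyl-CoA route, a closed TAG storage cycle (the
#' degradation leg shipped shut, to be opened by the ddTAG intervention),
#' a competing secondary-metabolite cluster draining acetyl-CoA, and a
#' biomass objective drawing sugar, acyl and cofactor currencies.
#' Metabolite ids are BiGG-style so the shipped module mappings apply.
#'
#' @param glucose_uptake Maximal glucose uptake (mmol/gDW/h).
#' @return A `gem_model`.
#' @export
make_host_toy <- function(glucose_uptake = 10) {
  mets <- rbind(
    metabolite("glc__D_c", "D-glucose", formula = "C6H12O6"),
    metabolite("g6p_c", "glucose 6-phosphate"),
    metabolite("g1p_c", "glucose 1-phosphate"),
    metabolite("pyr_c", "pyruvate"),
    metabolite("accoa_c", "acetyl-CoA"),
    metabolite("malcoa_c", "malonyl-CoA"),
    metabolite("ppcoa_c", "propionyl-CoA"),
    metabolite("mmcoa_c", "methylmalonyl-CoA"),
    metabolite("tag_c", "triacylglycerol storage"),
    metabolite("cda_c", "competing secondary metabolite"),
    metabolite("atp_c", "ATP"), metabolite("adp_c", "ADP"),
    metabolite("nadph_c", "NADPH"), metabolite("nadp_c", "NADP+"),
    metabolite("biomass_b", "biomass", compartment = "b", boundary = TRUE))
  rxns <- list(
    reaction("EX_glc__D_e", c(glc__D_c = 1), lb = 0, ub = glucose_uptake,
             name = "glucose uptake"),
    reaction("HEX1", c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
             lb = 0, ub = 1000, gpr = "glkA", name = "hexokinase"),
    reaction("PGMT", c(g6p_c = -1, g1p_c = 1), lb = -1000, ub = 1000,
             gpr = "pgm", name = "phosphoglucomutase"),
    reaction("GLYC", c(g6p_c = -1, adp_c = -2, nadp_c = -2,
                       pyr_c = 2, atp_c = 2, nadph_c = 2),
             lb = 0, ub = 1000, gpr = "pyk1", name = "glycolysis (lumped)"),
    reaction("PDH", c(pyr_c = -1, nadp_c = -1, accoa_c = 1, nadph_c = 1),
             lb = 0, ub = 1000, gpr = "pdhA and pdhB",
             name = "pyruvate dehydrogenase (lumped)"),
    reaction("ACC", c(accoa_c = -1, atp_c = -1, malcoa_c = 1, adp_c = 1),
             lb = 0, ub = 1000, gpr = "accA and accB",
             name = "acetyl-CoA carboxylase (lumped)"),
    reaction("PPS", c(pyr_c = -1, nadph_c = -1, ppcoa_c = 1, nadp_c = 1),
             lb = 0, ub = 1000, gpr = "prpE",
             name = "propionyl-CoA supply (lumped)"),
    reaction("PCC", c(ppcoa_c = -1, atp_c = -1, mmcoa_c = 1, adp_c = 1),
             lb = 0, ub = 1000, gpr = "pccA and pccB",
             name = "propionyl-CoA carboxylase (lumped)"),
    reaction("TCA", c(accoa_c = -1, nadp_c = -4, nadph_c = 4),
             lb = 0, ub = 1000, gpr = "citA and icd and sucA",
             name = "TCA cycle (lumped; CO2 untracked)"),
    reaction("OXPHOS", c(nadph_c = -1, adp_c = -2, nadp_c = 1, atp_c = 2),
             lb = 0, ub = 1000, name = "respiration (lumped)"),
    reaction("ATPM", c(atp_c = -1, adp_c = 1), lb = 0, ub = 1000,
             name = "ATP maintenance / sink"),
    reaction("TAGSYN", c(accoa_c = -3, atp_c = -1, tag_c = 1, adp_c = 1),
             lb = 0, ub = 1000, gpr = "sco6196up",
             name = "TAG storage synthesis (lumped)"),
    reaction("TAGDEG", c(tag_c = -1, accoa_c = 3), lb = 0, ub = 0,
             gpr = "sco6196", name = "TAG degradation (shipped closed)"),
    reaction("CDASYN", c(accoa_c = -2, atp_c = -1, cda_c = 1, adp_c = 1),
             lb = 0, ub = 1000, gpr = "cdaPS1",
             name = "competing secondary-metabolite cluster (lumped)"),
    reaction("EX_cda", c(cda_c = -1), lb = 0, ub = 1000,
             name = "competing metabolite export"),
    reaction("BIOMASS", c(g6p_c = -0.5, accoa_c = -0.3, atp_c = -2,
                          nadph_c = -0.4, adp_c = 2, nadp_c = 0.4,
                          biomass_b = 1),
             lb = 0, ub = 1000, name = "biomass"))
  metabolic_model(mets, rxns, biomass = "BIOMASS", id = "toy_host")
}

#' Graft mapping from module currencies to the desk-scale host
#'
#' Documents, species by species, how the module currencies resolve on
#' [make_host_toy()]: acyl-CoA and sugar-phosphate pools map to the host
#' pools of the same meaning; the TDP carrier is charged to the adenylate
#' pool (dTTP as ATP, dTDP released as ADP); CoA, SAM/SAH, ammonium,
#' water, protons, and pyrophosphate are dropped as freely buffered — the
#' desk-scale host does not track them.
#'
#' @return Named character vector for [graft_module()].
#' @export
toy_host_mapping <- function() {
  c(accoa_c = "accoa_c", malcoa_c = "malcoa_c", mmcoa_c = "mmcoa_c",
    ppcoa_c = "ppcoa_c", g1p_c = "g1p_c", pyr_c = "pyr_c",
    nadph_c = "nadph_c", nadp_c = "nadp_c",
    dttp_c = "atp_c", tdp_c = "adp_c",
    coa_c = NA, amet_c = NA, ahcys_c = NA, nh4_c = NA, h2o_c = NA,
    h_c = NA, ppi_c = NA)
}
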