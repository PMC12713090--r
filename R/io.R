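#' Read a metabolic model from file
#'
#' Two formats are supported: SBML Level 3 with the FBC package (bounds,
#' flux objectives, gene-product associations) and a minimal JSON dialect
#' used for hand-written fixtures:
#'
#' ```
#' {"id": ..., "metabolites": [{"id","name","compartment","formula",
#'  "charge","boundary"}, ...],
#'  "reactions": [{"id","name","mets": {met: coefficient},
#'  "lb","ub","gpr","subsystem"}, ...],
#'  "biomass": reaction-id, "objective": reaction-id}
#' ```
#'
#' Bounds default to +/-1000 mmol/gDW/h when a format omits them. The
#' objective is taken from the format's objective annotation when present
#' (FBC active objective, JSON `objective` key).
#'
#' @param path File path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by extension).
#' @param biomass_id Biomass reaction id override; for SBML files without
#'   one it defaults to the active objective.
#' @return A `gem_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       biomass_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
         json = read_model_json(path, biomass_id),
         sbml = read_model_sbml(path, biomass_id))
}

read_model_json <- function(path, biomass_id = NULL) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("JSON model ", path, " lacks 'metabolites' or 'reactions'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in ", path)
    metabolite(m$id,
               name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_,
               boundary = isTRUE(m$boundary))
  }))
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in ", path)
    if (is.null(r$mets) || length(r$mets) == 0L)
      stop("reaction '", r$id, "' in ", path, " has no stoichiometry")
    reaction(r$id, stoich = unlist(r$mets),
             lb = r$lb %||% -1000, ub = r$ub %||% 1000,
             name = r$name %||% r$id, gpr = r$gpr %||% "",
             subsystem = r$subsystem %||% "")
  })
  biomass <- biomass_id %||% doc$biomass %||% doc$objective
  if (is.null(biomass)) stop("JSON model ", path, " declares no biomass/objective")
  metabolic_model(mets, rxns, biomass = biomass,
                  objective = doc$objective %||% biomass,
                  id = doc$id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a metabolic model to file
#'
#' The emitted file re-reads (with [read_model()]) to a model equivalent in
#' ids, stoichiometry, bounds, gene rules, and objective annotations.
#'
#' @param model A valid `gem_model`.
#' @param path Output path.
#' @param format `"json"` or `"sbml"`.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (length(model$reactions) == 0L) stop("refusing to write a model with no reactions")
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    if (isTRUE(m$boundary)) out$boundary <- TRUE
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name, mets = as.list(r$stoich),
         lb = r$lb, ub = r$ub, gpr = r$gpr, subsystem = r$subsystem)
  })
  doc <- list(id = model$id, metabolites = mets, reactions = unname(rxns),
              biomass = model$biomass_reaction_id,
              objective = model$objective_reaction_id)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SBML Level 3 + FBC v2 ----

SBML_NS <- c(sbml = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

read_model_sbml <- function(path, biomass_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e)))
  ns <- SBML_NS
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  params <- xml2::xml_find_all(mdl, ".//sbml:listOfParameters/sbml:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(mdl, ".//sbml:listOfSpecies/sbml:species", ns)
  if (length(sp) == 0L) stop("no species in ", path)
  mets <- do.call(rbind, lapply(sp, function(s) {
    ch <- xml2::xml_attr(s, "charge", ns = ns)
    fch <- xml2::xml_attr(s, "fbc:charge", ns = ns)
    metabolite(xml2::xml_attr(s, "id"),
               name = xml2::xml_attr(s, "name") %|na|% xml2::xml_attr(s, "id"),
               compartment = xml2::xml_attr(s, "compartment") %|na|% "c",
               formula = xml2::xml_attr(s, "fbc:chemicalFormula", ns = ns),
               charge = as.integer(fch %|na|% ch),
               boundary = identical(xml2::xml_attr(s, "boundaryCondition"), "true"))
  }))

  rx <- xml2::xml_find_all(mdl, ".//sbml:listOfReactions/sbml:reaction", ns)
  if (length(rx) == 0L) stop("no reactions in ", path)
  rxns <- lapply(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(r, xp, ns)
      if (!length(nodes)) return(numeric())
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(nodes, "species"))
    }
    st <- c(refs("./sbml:listOfReactants/sbml:speciesReference", -1),
            refs("./sbml:listOfProducts/sbml:speciesReference", +1))
    if (length(st) == 0L)
      stop("SBML reaction '", rid, "' in ", path, " has no stoichiometry")
    # merge duplicated species (reactant and product sides)
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    st <- stats::setNames(as.numeric(st), names(st))
    lbp <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(r, "fbc:upperFluxBound", ns = ns)
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    gpa <- xml2::xml_find_first(r, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else sbml_gpa_to_rule(xml2::xml_child(gpa))
    reaction(rid, stoich = st, lb = lb, ub = ub,
             name = xml2::xml_attr(r, "name") %|na|% rid, gpr = gpr)
  })

  obj <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- if (!inherits(obj, "xml_missing"))
    xml2::xml_attr(obj, "fbc:reaction", ns = ns) else NULL
  biomass <- biomass_id %||% objective
  if (is.null(biomass))
    stop("SBML model ", path, " has no FBC objective; supply biomass_id")

  gps <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- if (length(gps)) {
    lab <- xml2::xml_attr(gps, "fbc:label", ns = ns)
    idg <- xml2::xml_attr(gps, "fbc:id", ns = ns)
    sort(unique(ifelse(is.na(lab), idg, lab)))
  } else NULL

  m <- metabolic_model(mets, rxns, biomass = biomass,
                       objective = objective %||% biomass, genes = NULL,
                       id = xml2::xml_attr(mdl, "id") %|na|%
                         tools::file_path_sans_ext(basename(path)))
  m
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

sbml_gpa_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    lab <- xml2::xml_attr(node, "label")
    return(lab %|na|% xml2::xml_attr(node, "geneProduct"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpa_to_rule, "")
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

write_model_sbml <- function(model, path) {
  b <- rxn_bounds(model)
  vals <- sort(unique(c(b)))
  fmt1 <- function(v) vapply(v, function(x) format(x, digits = 17), "")
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)), fmt1(vals))
  pname <- function(v) pid[[fmt1(v)]]

  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS[["sbml"]], SBML_NS[["fbc"]]),
    sprintf('  <model id="%s" fbc:strict="true">', xesc(model$id)),
    '    <listOfCompartments>')
  for (cp in unique(model$metabolites$compartment))
    xml <- c(xml, sprintf('      <compartment id="%s" constant="true"/>', xesc(cp)))
  xml <- c(xml, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    attrs <- sprintf('id="%s" name="%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"',
                     xesc(m$id), xesc(m$name), xesc(m$compartment),
                     if (isTRUE(m$boundary)) "true" else "false")
    if (!is.na(m$formula)) attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', xesc(m$formula)))
    if (!is.na(m$charge)) attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', m$charge))
    xml <- c(xml, sprintf('      <species %s/>', attrs))
  }
  xml <- c(xml, '    </listOfSpecies>', '    <listOfParameters>')
  for (v in vals)
    xml <- c(xml, sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                          pname(v), format(v, digits = 17)))
  xml <- c(xml, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    xml <- c(xml, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      xesc(r$id), xesc(r$name), if (r$lb < 0) "true" else "false",
      pname(r$lb), pname(r$ub)))
    neg <- r$stoich[r$stoich < 0]; pos <- r$stoich[r$stoich > 0]
    if (length(neg)) {
      xml <- c(xml, '        <listOfReactants>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       xesc(names(neg)), format(-unname(neg), digits = 17)),
               '        </listOfReactants>')
    }
    if (length(pos)) {
      xml <- c(xml, '        <listOfProducts>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       xesc(names(pos)), format(unname(pos), digits = 17)),
               '        </listOfProducts>')
    }
    if (nzchar(r$gpr))
      xml <- c(xml, '        <fbc:geneProductAssociation>',
               rule_to_sbml_gpa(r$gpr, indent = "          "),
               '        </fbc:geneProductAssociation>')
    xml <- c(xml, '      </reaction>')
  }
  xml <- c(xml, '    </listOfReactions>')
  if (length(model$genes)) {
    xml <- c(xml, '    <fbc:listOfGeneProducts>',
             sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                     gsub("[^A-Za-z0-9_]", "_", model$genes), xesc(model$genes)),
             '    </fbc:listOfGeneProducts>')
  }
  xml <- c(xml,
           '    <fbc:listOfObjectives fbc:activeObjective="obj">',
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           '        <fbc:listOfFluxObjectives>',
           sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                   xesc(model$objective_reaction_id)),
           '        </fbc:listOfFluxObjectives>',
           '      </fbc:objective>',
           '    </fbc:listOfObjectives>',
           '  </model>', '</sbml>')
  writeLines(xml, path)
}

xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# Emit an fbc geneProductAssociation subtree for a parsed rule.
rule_to_sbml_gpa <- function(gpr, indent = "") {
  ast <- parse_gpr_ast(gpr)
  emit <- function(node, ind) {
    if (is.character(node))
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s" label="%s"/>',
                     ind, gsub("[^A-Za-z0-9_]", "_", node), xesc(node)))
    tag <- paste0("fbc:", node$op)
    c(sprintf("%s<%s>", ind, tag),
      unlist(lapply(node$args, emit, ind = paste0(ind, "  "))),
      sprintf("%s</%s>", ind, tag))
  }
  emit(ast, indent)
}

# Minimal recursive-descent parser for gene rules -> AST
# (character leaf, or list(op = "and"/"or", args = list(...))).
parse_gpr_ast <- function(gpr) {
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[A-Za-z0-9_.:-]+", gpr))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("malformed gene rule: ", gpr)
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")")) stop("unbalanced parentheses in gene rule: ", gpr)
      return(e)
    }
    if (t %in% c(")") || tolower(t) %in% c("and", "or"))
      stop("malformed gene rule: ", gpr)
    t
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("malformed gene rule: ", gpr)
  out
}
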