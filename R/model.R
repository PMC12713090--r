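#' Construct a metabolite
#'
#' Metabolites are the nodes of the stoichiometric network. A metabolite
#' flagged `boundary = TRUE` (the SBML `boundaryCondition` convention) is
#' excluded from steady-state mass balance; biomass sinks in the toy
#' fixtures use this.
#'
#' @param id Unique identifier within a model.
#' @param name Human-readable name.
#' @param compartment Compartment tag (non-empty).
#' @param formula Optional elemental formula, e.g. `"C6H12O6"`.
#' @param charge Optional integer charge.
#' @param boundary Logical; exclude from mass balance.
#' @return A one-row data frame usable in [metabolic_model()].
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_,
                       charge = NA_integer_, boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(compartment)) stop("metabolite '", id, "': compartment must be non-empty")
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula), charge = as.integer(charge),
             boundary = isTRUE(boundary), stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' @param id Unique identifier.
#' @param stoich Named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed). Must be non-empty with non-zero coefficients.
#' @param lb,ub Flux bounds in mmol/gDW/h; `lb <= ub`.
#' @param name Human-readable name.
#' @param gpr Gene rule, a boolean expression over gene ids with
#'   `and`/`or` and parentheses; `""` for none.
#' @param subsystem Subsystem tag.
#' @return A list of class `gem_reaction`.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, name = id, gpr = "",
                     subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) == 0L) stop("reaction '", id, "': stoichiometry is empty")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a named vector")
  if (any(stoich == 0)) stop("reaction '", id, "': zero stoichiometric coefficient")
  if (anyDuplicated(names(stoich))) stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  if (!is.finite(lb) && lb != -Inf) stop("reaction '", id, "': bad lower bound")
  if (lb > ub) stop("reaction '", id, "': lower_bound ", lb, " > upper_bound ", ub)
  structure(list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
                 gpr = gpr, subsystem = subsystem),
            class = "gem_reaction")
}

#' Assemble a metabolic model
#'
#' @param metabolites Data frame from rbinding [metabolite()] rows, or a list
#'   of such rows.
#' @param reactions List of [reaction()] objects.
#' @param biomass Id of the biomass reaction.
#' @param objective Id of the objective reaction (defaults to `biomass`).
#' @param genes Character vector of gene ids; derived from gene rules when
#'   `NULL`.
#' @param id Model identifier.
#' @return An object of class `gem_model`.
#' @export
metabolic_model <- function(metabolites, reactions, biomass,
                            objective = biomass, genes = NULL, id = "model") {
  if (is.list(metabolites) && !is.data.frame(metabolites))
    metabolites <- do.call(rbind, metabolites)
  stopifnot(is.data.frame(metabolites))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (length(reactions) == 0L) stop("model must contain at least one reaction")
  rids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  missing_mets <- setdiff(used, metabolites$id)
  if (length(missing_mets))
    stop("reactions reference undeclared metabolites: ",
         paste(missing_mets, collapse = ", "))
  if (!biomass %in% rids) stop("biomass reaction '", biomass, "' not in model")
  if (!objective %in% rids) stop("objective reaction '", objective, "' not in model")
  rule_genes <- unique(unlist(lapply(reactions, function(r) {
    g <- tryCatch(gpr_genes(r$gpr), error = function(e) character())
    g
  })))
  if (is.null(genes)) genes <- sort(rule_genes)
  else {
    extra <- setdiff(rule_genes, genes)
    if (length(extra))
      stop("gene rules use undeclared genes: ", paste(extra, collapse = ", "))
  }
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 genes = genes, biomass_reaction_id = biomass,
                 objective_reaction_id = objective),
            class = "gem_model")
}

#' @export
print.gem_model <- function(x, ...) {
  cat("<gem_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      " (", sum(x$metabolites$boundary), " boundary)\n",
      "  reactions:   ", length(x$reactions),
      " (", sum(is_exchange(x)), " exchange)\n",
      "  genes:       ", length(x$genes), "\n",
      "  biomass:     ", x$biomass_reaction_id, "\n",
      "  objective:   ", x$objective_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Reaction and metabolite ids
#' @param model A `gem_model`.
#' @return Character vector of ids in stable (insertion) order.
#' @export
rxn_ids <- function(model) names(model$reactions)

#' @rdname rxn_ids
#' @export
met_ids <- function(model) model$metabolites$id

#' Which reactions are exchange reactions?
#'
#' An exchange (boundary) reaction has exactly one metabolite in its
#' stoichiometry.
#'
#' @param model A `gem_model`.
#' @return Named logical vector over reactions.
#' @export
is_exchange <- function(model) {
  vapply(model$reactions, function(r) length(r$stoich) == 1L, NA)
}

#' Reaction bounds as a two-column matrix
#' @param model A `gem_model`.
#' @return Matrix with columns `lb`, `ub`, rownames = reaction ids.
#' @export
rxn_bounds <- function(model) {
  cbind(lb = vapply(model$reactions, function(r) r$lb, 0),
        ub = vapply(model$reactions, function(r) r$ub, 0))
}

#' Stoichiometric matrix
#'
#' Sparse matrix S with one row per non-boundary metabolite (model order)
#' and one column per reaction (model order); `S[m, r]` is the coefficient
#' of metabolite `m` in reaction `r`. Boundary metabolites are excluded
#' from mass balance, matching the SBML `boundaryCondition` semantics.
#'
#' @param model A `gem_model`.
#' @param include_boundary Keep rows for boundary metabolites.
#' @return A `Matrix::sparseMatrix` with dimnames.
#' @export
stoichiometric_matrix <- function(model, include_boundary = FALSE) {
  mets <- model$metabolites
  if (!include_boundary) mets <- mets[!mets$boundary, , drop = FALSE]
  midx <- stats::setNames(seq_len(nrow(mets)), mets$id)
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(model$reactions)) {
    st <- model$reactions[[k]]$stoich
    keep <- names(st) %in% mets$id
    st <- st[keep]
    i <- c(i, midx[names(st)])
    j <- c(j, rep.int(k, length(st)))
    x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(nrow(mets), length(model$reactions)),
                       dimnames = list(mets$id, names(model$reactions)))
}

# Parse an elemental formula like "C6H12O6" into a named count vector.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != formula)
    stop("cannot parse formula '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- as.numeric(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1
  tapply(n, el, sum)
}

# Extract gene ids from a boolean gene rule; errors on malformed rules.
#' Genes referenced by a gene rule
#' @param gpr Rule string, e.g. `"(g1 and g2) or g3"`.
#' @return Character vector of gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character())
  s <- gsub("[()]", " ", gpr)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  ops <- tolower(toks) %in% c("and", "or")
  # structural checks on the original string
  bal <- 0L
  for (ch in strsplit(gpr, "")[[1]]) {
    if (ch == "(") bal <- bal + 1L
    if (ch == ")") bal <- bal - 1L
    if (bal < 0L) stop("unbalanced parentheses in gene rule: ", gpr)
  }
  if (bal != 0L) stop("unbalanced parentheses in gene rule: ", gpr)
  if (length(toks) == 0L) return(character())
  # operators must alternate with operands
  if (ops[1L] || ops[length(ops)] || any(ops[-1L] & ops[-length(ops)]))
    stop("malformed gene rule: ", gpr)
  if (length(ops) > 1L && any(!ops[-1L] & !ops[-length(ops)]))
    stop("malformed gene rule (adjacent operands): ", gpr)
  if (!any(!ops)) stop("malformed gene rule: ", gpr)
  genes <- toks[!ops]
  bad <- grepl("[^A-Za-z0-9_.:-]", genes)
  if (any(bad)) stop("bad gene token(s) in rule: ", paste(genes[bad], collapse = ", "))
  unique(genes)
}

#' Structural validation of a model
#'
#' Reports dangling metabolites (declared but used by no reaction),
#' elementally unbalanced internal reactions (only when every participating
#' metabolite carries a formula; exchange, biomass, and sink/demand
#' pseudo-reactions — all coefficients of one sign — are exempt),
#' bound violations, and unparsable gene rules. `is_solvable` is `TRUE` when
#' the all-zero flux vector is feasible (every reaction admits zero flux)
#' and the matrix is well-formed.
#'
#' @param model A `gem_model`.
#' @return A list of class `gem_validation`.
#' @export
validate_model <- function(model) {
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  dangling <- setdiff(model$metabolites$id, used)

  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  exch <- is_exchange(model)
  unbal <- data.frame(reaction_id = character(), element = character(),
                      imbalance = numeric(), stringsAsFactors = FALSE)
  for (r in model$reactions) {
    if (exch[[r$id]] || r$id == model$biomass_reaction_id) next
    if (all(r$stoich > 0) || all(r$stoich < 0)) next  # sink/demand pseudo-reaction
    fs <- fmap[names(r$stoich)]
    if (any(is.na(fs)) || any(!nzchar(fs))) next
    counts <- list()
    ok <- TRUE
    for (k in seq_along(r$stoich)) {
      f <- tryCatch(parse_formula(fs[[k]]), error = function(e) NULL)
      if (is.null(f)) { ok <- FALSE; break }
      for (el in names(f)) {
        counts[[el]] <- (if (is.null(counts[[el]])) 0 else counts[[el]]) +
          r$stoich[[k]] * f[[el]]
      }
    }
    if (!ok) next
    for (el in names(counts)) {
      if (abs(counts[[el]]) > 1e-9)
        unbal <- rbind(unbal, data.frame(reaction_id = r$id, element = el,
                                         imbalance = counts[[el]],
                                         stringsAsFactors = FALSE))
    }
  }

  b <- rxn_bounds(model)
  bviol <- rownames(b)[b[, "lb"] > b[, "ub"]]

  gerr <- character()
  for (r in model$reactions) {
    e <- tryCatch({ gpr_genes(r$gpr); NULL }, error = function(e) conditionMessage(e))
    if (!is.null(e)) gerr <- c(gerr, paste0(r$id, ": ", e))
  }

  zero_ok <- all(b[, "lb"] <= 0 & b[, "ub"] >= 0)
  structure(list(dangling_metabolites = dangling,
                 unbalanced_reactions = unbal,
                 bound_violations = bviol,
                 gpr_parse_errors = gerr,
                 is_solvable = zero_ok && length(bviol) == 0L),
            class = "gem_validation")
}

#' @export
print.gem_validation <- function(x, ...) {
  cat("<gem_validation>\n",
      "  dangling metabolites: ", length(x$dangling_metabolites), "\n",
      "  unbalanced reactions: ", nrow(x$unbalanced_reactions), "\n",
      "  bound violations:     ", length(x$bound_violations), "\n",
      "  gene-rule errors:     ", length(x$gpr_parse_errors), "\n",
      "  solvable:             ", x$is_solvable, "\n", sep = "")
  invisible(x)
}

#' Is a validation report clean?
#' @param report A `gem_validation`.
#' @return Logical.
#' @export
is_clean_report <- function(report) {
  length(report$dangling_metabolites) == 0L &&
    nrow(report$unbalanced_reactions) == 0L &&
    length(report$bound_violations) == 0L &&
    length(report$gpr_parse_errors) == 0L &&
    isTRUE(report$is_solvable)
}

#' Replace a reaction's bounds
#'
#' @param model A `gem_model`.
#' @param reaction_id Reaction id.
#' @param lb,ub New bounds; `NULL` leaves a bound unchanged.
#' @return The modified copy of the model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  if (!reaction_id %in% names(model$reactions))
    stop("unknown reaction id: ", reaction_id)
  r <- model$reactions[[reaction_id]]
  if (!is.null(lb)) r$lb <- lb
  if (!is.null(ub)) r$ub <- ub
  if (r$lb > r$ub) stop("set_bounds would leave lb > ub on ", reaction_id)
  model$reactions[[reaction_id]] <- r
  model
}

#' Set the growth medium of a model
#'
#' Opens the listed exchange reactions to uptake at the given maximal rates
#' and closes uptake through every other carbon-source exchange. An exchange
#' is treated as a carbon source iff its metabolite's formula contains
#' carbon and the formula is not on the inorganic whitelist. Exchanges whose
#' metabolite has no formula, and non-carbon exchanges (water, ions,
#' ammonium, oxygen, ...), are left untouched. Stoichiometry is never
#' altered, only bounds; the input model is not modified.
#'
#' Uptake direction follows the exchange's stoichiometry: for the usual
#' `A ->` export form (coefficient -1) uptake is negative flux and the
#' uptake bound is the lower bound; for the `-> A` import form
#' (coefficient +1) uptake is positive flux and the uptake bound is the
#' upper bound.
#'
#' @param model A `gem_model`.
#' @param uptake Named numeric vector / list, exchange reaction id -> maximal
#'   uptake rate (non-negative, mmol/gDW/h).
#' @param inorganic_formulas Carbon-containing formulas exempted from
#'   carbon-source closing (CO2 handling is configured here).
#' @return A modified copy of the model.
#' @export
set_medium <- function(model, uptake,
                       inorganic_formulas = c("CO2", "HCO3", "CO3")) {
  uptake <- unlist(uptake)
  if (length(uptake) && is.null(names(uptake)))
    stop("uptake map must be named by exchange reaction id")
  exch <- is_exchange(model)
  unknown <- setdiff(names(uptake), names(model$reactions))
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  not_exch <- names(uptake)[!exch[names(uptake)]]
  if (length(not_exch))
    stop("not exchange reaction(s): ", paste(not_exch, collapse = ", "))
  if (any(uptake < 0)) stop("uptake rates must be non-negative")

  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  is_carbon_source <- function(rid) {
    met <- names(model$reactions[[rid]]$stoich)
    f <- fmap[[met]]
    if (is.na(f) || !nzchar(f)) return(FALSE)
    if (f %in% inorganic_formulas) return(FALSE)
    cnt <- tryCatch(parse_formula(f), error = function(e) NULL)
    !is.null(cnt) && "C" %in% names(cnt)
  }
  set_uptake <- function(m, rid, rate) {
    coefficient <- m$reactions[[rid]]$stoich[[1L]]
    if (coefficient < 0) {             # export form: uptake = negative flux
      set_bounds(m, rid, lb = -rate)
    } else {                           # import form: uptake = positive flux
      set_bounds(m, rid, ub = rate)
    }
  }
  out <- model
  for (rid in names(model$reactions)[exch]) {
    if (rid %in% names(uptake)) {
      out <- set_uptake(out, rid, unname(uptake[[rid]]))
    } else if (is_carbon_source(rid)) {
      out <- set_uptake(out, rid, 0)
    }
  }
  out
}
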