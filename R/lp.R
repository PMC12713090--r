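#' Fixed-flux constraint
#'
#' Pins a reaction's flux to a value. Implemented as the interval
#' `value +/- 1e-9 * max(1, |value|)` rather than strict equality, which is
#' numerically brittle.
#'
#' @param reaction_id Reaction id.
#' @param value Flux value to pin to.
#' @return A list of class `fixed_constraint`.
#' @export
fixed_constraint <- function(reaction_id, value) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L,
            is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(reaction_id = reaction_id, value = value),
            class = "fixed_constraint")
}

PIN_TOL <- 1e-9
BIG_BOUND <- 1e6

#' Flux distribution
#'
#' One LP solution: reaction fluxes, the achieved objective, and a solver
#' status. When `status == "optimal"`, `S v = 0` holds within 1e-6 and every
#' flux is within its bounds (up to tolerance).
#'
#' @param fluxes Named numeric vector, reaction id -> flux.
#' @param objective_value Achieved objective.
#' @param status `"optimal"`, `"infeasible"`, or `"unbounded"`.
#' @return A list of class `flux_distribution`.
#' @export
flux_distribution <- function(fluxes, objective_value, status) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status=", x$status,
      " objective=", format(x$objective_value), "\n", sep = "")
  if (x$status == "optimal") {
    nz <- x$fluxes[abs(x$fluxes) > 1e-9]
    cat("  ", length(nz), " of ", length(x$fluxes),
        " reactions carry flux\n", sep = "")
  }
  invisible(x)
}

# Narrow model bounds by fixed constraints. Returns list(lb, ub) or NULL
# when a constraint is trivially incompatible with the reaction's bounds
# (reported upstream as infeasible).
constrained_bounds <- function(model, constraints) {
  b <- rxn_bounds(model)
  lb <- b[, "lb"]; ub <- b[, "ub"]
  for (ct in constraints) {
    if (!inherits(ct, "fixed_constraint"))
      stop("constraints must be fixed_constraint objects")
    rid <- ct$reaction_id
    if (!rid %in% rownames(b)) stop("unknown reaction id in constraint: ", rid)
    tol <- PIN_TOL * max(1, abs(ct$value))
    nlb <- max(lb[[rid]], ct$value - tol)
    nub <- min(ub[[rid]], ct$value + tol)
    if (nlb > nub) return(NULL)
    lb[[rid]] <- nlb; ub[[rid]] <- nub
  }
  list(lb = lb, ub = ub)
}

# Core bounded-variable LP over the steady-state polytope:
#   optimize obj . v  subject to  S v = 0,  lb <= v <= ub.
# Delegates to the package's deterministic dense simplex (R/simplex.R).
solve_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n, ncol(S) == n)
  res <- fs_lp(S, lb, ub, obj, maximize = maximize, big = BIG_BOUND)
  list(status = res$status, x = res$v, value = res$value)
}

#' Maximize (or minimize) the flux of one reaction
#'
#' Flux balance analysis: optimizes the stated reaction's flux subject to
#' steady-state mass balance, the model's bounds, and any fixed-flux
#' constraints. Infeasibility and unboundedness are reported in the status,
#' not raised as errors.
#'
#' @param model A `gem_model`.
#' @param objective_reaction_id Reaction whose flux is optimized.
#' @param constraints List of [fixed_constraint()]s.
#' @param sense `"max"` or `"min"`.
#' @return A [flux_distribution()].
#' @export
maximize_flux <- function(model, objective_reaction_id = model$objective_reaction_id,
                          constraints = list(), sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!objective_reaction_id %in% names(model$reactions))
    stop("unknown objective reaction: ", objective_reaction_id)
  cb <- constrained_bounds(model, constraints)
  rids <- rxn_ids(model)
  if (is.null(cb))
    return(flux_distribution(stats::setNames(rep(NA_real_, length(rids)), rids),
                             NA_real_, "infeasible"))
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(rids == objective_reaction_id)
  sol <- solve_lp(S, cb$lb, cb$ub, obj, maximize = (sense == "max"))
  if (sol$status != "optimal")
    return(flux_distribution(stats::setNames(rep(NA_real_, length(rids)), rids),
                             NA_real_, sol$status))
  flux_distribution(stats::setNames(sol$x, rids), sol$value, "optimal")
}

#' Parsimonious flux balance analysis
#'
#' Among all flux vectors satisfying mass balance, the bounds, and the given
#' fixed-flux constraints, returns one minimizing total absolute flux
#' `sum(|v|)`. Implemented the standard way: every reversible reaction is
#' split into non-negative forward and backward halves, both penalized at
#' unit cost, and the halves are re-merged in the returned distribution.
#' `objective_value` is the achieved `sum(|v|)`.
#'
#' @inheritParams maximize_flux
#' @return A [flux_distribution()].
#' @export
pfba <- function(model, constraints = list()) {
  cb <- constrained_bounds(model, constraints)
  rids <- rxn_ids(model)
  nas <- stats::setNames(rep(NA_real_, length(rids)), rids)
  if (is.null(cb)) return(flux_distribution(nas, NA_real_, "infeasible"))
  lb <- ifelse(is.finite(cb$lb), cb$lb, -BIG_BOUND)
  ub <- ifelse(is.finite(cb$ub), cb$ub, BIG_BOUND)
  S <- as.matrix(stoichiometric_matrix(model))
  n <- length(rids)

  # build split system: columns and their signs per original reaction
  cols <- list(); owner <- integer(); sgn <- numeric()
  slb <- numeric(); sub <- numeric()
  for (k in seq_len(n)) {
    if (lb[k] >= 0) {                       # forward only
      cols <- c(cols, list(S[, k])); owner <- c(owner, k); sgn <- c(sgn, 1)
      slb <- c(slb, lb[k]); sub <- c(sub, ub[k])
    } else if (ub[k] <= 0) {                # backward only
      cols <- c(cols, list(-S[, k])); owner <- c(owner, k); sgn <- c(sgn, -1)
      slb <- c(slb, -ub[k]); sub <- c(sub, -lb[k])
    } else {                                # genuinely reversible: split
      cols <- c(cols, list(S[, k], -S[, k]))
      owner <- c(owner, k, k); sgn <- c(sgn, 1, -1)
      slb <- c(slb, 0, 0); sub <- c(sub, ub[k], -lb[k])
    }
  }
  Ssplit <- do.call(cbind, cols)
  obj <- rep(1, length(owner))
  sol <- solve_lp(Ssplit, slb, sub, obj, maximize = FALSE)
  if (sol$status != "optimal")
    return(flux_distribution(nas, NA_real_, sol$status))
  v <- numeric(n)
  for (j in seq_along(owner)) v[owner[j]] <- v[owner[j]] + sgn[j] * sol$x[j]
  flux_distribution(stats::setNames(v, rids), sum(abs(v)), "optimal")
}

#' Production envelope
#'
#' For each fraction `f` of the maximal biomass flux, pins biomass to
#' `f * max` and maximizes the target reaction, tracing the upper boundary
#' of the attainable (growth, production) region.
#'
#' @param model A `gem_model`.
#' @param biomass_reaction_id,target_reaction_id Reaction ids.
#' @param fractions Sorted numeric vector in `[0, 1]`.
#' @return Data frame with columns `fraction`, `biomass`, `target_max`,
#'   `status`, rows in input order.
#' @export
production_envelope <- function(model,
                                biomass_reaction_id = model$biomass_reaction_id,
                                target_reaction_id,
                                fractions = seq(0.2, 0.8, by = 0.1)) {
  stopifnot(all(fractions >= 0), all(fractions <= 1),
            !is.unsorted(fractions))
  mu <- maximize_flux(model, biomass_reaction_id)
  if (mu$status != "optimal")
    stop("model has no optimal growth solution (status ", mu$status, ")")
  mu_max <- mu$objective_value
  out <- lapply(fractions, function(f) {
    sol <- maximize_flux(model, target_reaction_id,
                         constraints = list(fixed_constraint(biomass_reaction_id,
                                                             f * mu_max)))
    data.frame(fraction = f, biomass = f * mu_max,
               target_max = sol$objective_value, status = sol$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
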