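#' Configuration for an enforced-objective flux scan
#'
#' The scan pins biomass at stepwise fractions of its theoretical maximum
#' (default 20% to 80% in steps of 10%), maximizes the target flux at each
#' level, pins it there, and takes the parsimonious (minimum total flux)
#' distribution at every level.
#'
#' @param biomass_reaction_id,target_reaction_id Reaction ids.
#' @param fractions Strictly increasing values in (0, 1).
#' @param use_pfba_for_control Apply parsimonious FBA to the pure-growth
#'   control as well (biomass pinned at its max); default `TRUE`, for
#'   comparability with the enforced levels.
#' @param activation_epsilon Fluxes below this magnitude count as zero.
#' @param deadband Half-width of the neutral band around score 1; scores in
#'   `[1 - deadband, 1 + deadband]` are classified neutral.
#' @param aggregation `"mean_flux"` (default): score = |mean level flux| /
#'   |control flux|. `"mean_ratio"`: mean over levels of the per-level
#'   flux ratio. Identical when the control flux is constant; mean-of-flux
#'   is the more robust default when control flux is small.
#' @param gene_only Exclude reactions without a gene rule from the target
#'   lists.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(biomass_reaction_id, target_reaction_id,
                        fractions = seq(0.2, 0.8, by = 0.1),
                        use_pfba_for_control = TRUE,
                        activation_epsilon = 1e-6,
                        deadband = 0.05,
                        aggregation = c("mean_flux", "mean_ratio"),
                        gene_only = FALSE) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(fractions) >= 1, all(fractions > 0), all(fractions < 1),
            all(diff(fractions) > 0), activation_epsilon > 0, deadband >= 0)
  structure(list(biomass_reaction_id = biomass_reaction_id,
                 target_reaction_id = target_reaction_id,
                 fractions = fractions,
                 use_pfba_for_control = use_pfba_for_control,
                 activation_epsilon = activation_epsilon,
                 deadband = deadband, aggregation = aggregation,
                 gene_only = gene_only),
            class = "scan_config")
}

#' Pure-growth control distribution
#'
#' Maximizes biomass with the target left unconstrained (0% production,
#' 100% growth). With `use_pfba_for_control` the reported distribution is
#' the parsimonious one at maximal growth.
#'
#' @param model A `gem_model`.
#' @param config A [scan_config()].
#' @return A [flux_distribution()]; `objective_value` is the biomass flux.
#' @export
run_control <- function(model, config) {
  mu <- maximize_flux(model, config$biomass_reaction_id)
  if (mu$status != "optimal") return(mu)
  if (!config$use_pfba_for_control) return(mu)
  sol <- pfba(model, list(fixed_constraint(config$biomass_reaction_id,
                                           mu$objective_value)))
  if (sol$status != "optimal") return(sol)
  flux_distribution(sol$fluxes, mu$objective_value, "optimal")
}

#' Run the enforced-objective scan
#'
#' For each fraction `f`: biomass is pinned at `f` times its theoretical
#' maximum, the target flux is maximized, pinned at that per-level optimum,
#' and parsimonious FBA selects the reported distribution. An infeasible
#' level is recorded and the scan continues. A warning is attached when the
#' target is unreachable (max target flux not positive at the smallest
#' fraction).
#'
#' @param model A `gem_model`.
#' @param config A [scan_config()].
#' @return A list of class `fseof_scan`: `config`, `control`,
#'   `max_biomass`, `levels` (fraction -> [flux_distribution()]),
#'   `target_max_per_level`.
#' @export
run_scan <- function(model, config) {
  stopifnot(inherits(config, "scan_config"))
  for (rid in c(config$biomass_reaction_id, config$target_reaction_id))
    if (!rid %in% rxn_ids(model)) stop("unknown reaction id: ", rid)
  mu <- maximize_flux(model, config$biomass_reaction_id)
  if (mu$status != "optimal")
    stop("model infeasible under its medium (status ", mu$status, ")")
  mu_max <- mu$objective_value
  control <- run_control(model, config)

  levels <- list()
  target_max <- stats::setNames(rep(NA_real_, length(config$fractions)),
                                format(config$fractions))
  for (i in seq_along(config$fractions)) {
    f <- config$fractions[i]
    key <- format(f)
    pin_b <- fixed_constraint(config$biomass_reaction_id, f * mu_max)
    sol_t <- maximize_flux(model, config$target_reaction_id, list(pin_b))
    if (sol_t$status != "optimal") {
      levels[[key]] <- sol_t
      next
    }
    target_max[key] <- sol_t$objective_value
    sol <- pfba(model, list(pin_b, fixed_constraint(config$target_reaction_id,
                                                    sol_t$objective_value)))
    levels[[key]] <- if (sol$status == "optimal")
      flux_distribution(sol$fluxes, sol$objective_value, "optimal") else sol
  }
  scan <- structure(list(config = config, control = control,
                         max_biomass = mu_max, levels = levels,
                         target_max_per_level = target_max),
                    class = "fseof_scan")
  first_ok <- which(!is.na(target_max))
  if (length(first_ok) == 0L || target_max[first_ok[1]] <= config$activation_epsilon)
    warning("target '", config$target_reaction_id,
            "' is unreachable at the smallest enforced fraction")
  scan
}

#' @export
print.fseof_scan <- function(x, ...) {
  ok <- vapply(x$levels, function(l) l$status == "optimal", NA)
  cat("<fseof_scan> ", length(x$levels), " levels (",
      sum(ok), " optimal), max biomass ", format(x$max_biomass), "\n", sep = "")
  invisible(x)
}

#' Flux matrix of a scan
#'
#' @param scan A `fseof_scan`.
#' @return Numeric matrix, reactions x (levels + control); `NA` columns for
#'   infeasible levels.
#' @export
scan_matrix <- function(scan) {
  rids <- names(scan$control$fluxes)
  cols <- c(lapply(scan$levels, function(l) l$fluxes[rids]),
            list(control = scan$control$fluxes[rids]))
  m <- do.call(cbind, cols)
  rownames(m) <- rids
  colnames(m) <- c(paste0("f", names(scan$levels)), "control")
  m
}

#' Score reactions from a scan
#'
#' The score of a reaction is the ratio of its flux under the
#' biomass-enforced production regime to its flux under pure biomass
#' maximization: production-regime fluxes are averaged (signed) over the
#' optimal levels and divided by the absolute control flux. Scores are only
#' formed when the two regimes agree in sign; a reaction with zero control
#' flux but production-regime flux above `activation_epsilon` is marked
#' `ACTIVATED` (the fate of a heterologous module); a sign flip withholds
#' the score; a reaction inactive in both regimes scores 0 with reason
#' `"inactive"`.
#'
#' @param scan A `fseof_scan` with at least one optimal level and an
#'   optimal control.
#' @return Data frame of class `fseof_scores`: `reaction_id`, `score`
#'   (`NA` when activated or withheld), `activated`, `control_flux`,
#'   `production_flux_mean`, `direction_consistent`, `reason`, and the
#'   per-level flux columns.
#' @export
score_reactions <- function(scan) {
  stopifnot(inherits(scan, "fseof_scan"))
  if (scan$control$status != "optimal") stop("scan control is not optimal")
  ok <- vapply(scan$levels, function(l) l$status == "optimal", NA)
  if (!any(ok)) stop("scan has no optimal level")
  eps <- scan$config$activation_epsilon
  agg <- scan$config$aggregation
  rids <- names(scan$control$fluxes)
  lev <- vapply(scan$levels[ok], function(l) l$fluxes[rids], numeric(length(rids)))
  if (is.null(dim(lev))) lev <- matrix(lev, nrow = length(rids))
  control <- scan$control$fluxes[rids]
  pmean <- rowMeans(lev)

  score <- rep(NA_real_, length(rids))
  activated <- rep(FALSE, length(rids))
  dc <- rep(TRUE, length(rids))
  reason <- rep("", length(rids))
  for (i in seq_along(rids)) {
    c0 <- control[i]; pm <- pmean[i]
    if (abs(c0) <= eps && abs(pm) <= eps) {
      score[i] <- 0; reason[i] <- "inactive"
    } else if (abs(c0) <= eps) {
      activated[i] <- TRUE; reason[i] <- "activated"
    } else if (abs(pm) <= eps) {
      score[i] <- 0; reason[i] <- "zero_production_flux"
    } else if (sign(pm) != sign(c0)) {
      dc[i] <- FALSE; reason[i] <- "direction_flip"
    } else {
      score[i] <- if (agg == "mean_flux") abs(pm) / abs(c0)
                  else mean(lev[i, ] / c0)
      reason[i] <- "scored"
    }
  }
  out <- data.frame(reaction_id = rids, score = score, activated = activated,
                    control_flux = unname(control),
                    production_flux_mean = unname(pmean),
                    direction_consistent = dc, reason = reason,
                    stringsAsFactors = FALSE)
  levnames <- paste0("flux_f", names(scan$levels)[ok])
  out[levnames] <- lev
  attr(out, "config") <- scan$config
  class(out) <- c("fseof_scores", class(out))
  out
}

#' Classify reactions into overexpression and attenuation targets
#'
#' Up targets: `ACTIVATED` reactions first (ranked by mean production
#' flux), then scores above `1 + deadband` (ranked by score, descending).
#' Down targets: scores strictly between 0 and `1 - deadband` with nonzero
#' control flux, ranked ascending (strongest attenuation first). The
#' biomass reaction, the scan target, exchange reactions,
#' direction-inconsistent, inactive, and neutral reactions are excluded
#' with reasons (plus gene-less reactions when `gene_only` is set).
#'
#' @param scores A `fseof_scores` data frame.
#' @param model The scanned `gem_model`.
#' @param config The [scan_config()] used (defaults to the one attached to
#'   `scores`).
#' @return A list of class `fseof_targets` with ranked `up` and `down`
#'   data frames and an `excluded` data frame with reasons.
#' @export
classify_targets <- function(scores, model, config = attr(scores, "config")) {
  stopifnot(inherits(scores, "fseof_scores"), inherits(config, "scan_config"))
  delta <- config$deadband
  exch <- is_exchange(model)
  genes <- vapply(scores$reaction_id, function(rid)
    paste(gpr_genes(model$reactions[[rid]]$gpr), collapse = "; "), "")

  excl_reason <- rep(NA_character_, nrow(scores))
  mark <- function(cond, why) {
    hit <- cond & is.na(excl_reason)
    excl_reason[hit] <<- why
  }
  mark(scores$reaction_id == config$biomass_reaction_id, "biomass reaction")
  mark(scores$reaction_id == config$target_reaction_id, "scan target")
  mark(exch[scores$reaction_id], "exchange reaction")
  mark(!scores$direction_consistent, "direction inconsistent")
  mark(scores$reason == "inactive", "inactive")
  mark(scores$reason == "zero_production_flux", "no production-regime flux")
  if (config$gene_only) mark(!nzchar(genes), "no gene rule")

  free <- is.na(excl_reason)
  is_up <- free & (scores$activated |
                     (!is.na(scores$score) & scores$score > 1 + delta))
  is_down <- free & !scores$activated & !is.na(scores$score) &
    scores$score > 0 & scores$score < 1 - delta
  mark(free & !is_up & !is_down, "neutral")

  levcols <- grep("^flux_f", names(scores), value = TRUE)
  pick <- function(idx) {
    d <- scores[idx, c("reaction_id", "score", "activated", "control_flux",
                       "production_flux_mean", levcols)]
    d$genes <- genes[idx]
    d
  }
  up <- pick(which(is_up))
  up <- up[order(-up$activated, -ifelse(up$activated,
                                        up$production_flux_mean, -Inf),
                 -ifelse(up$activated, 0, up$score)), , drop = FALSE]
  down <- pick(which(is_down))
  down <- down[order(down$score), , drop = FALSE]
  if (nrow(up)) up$rank <- seq_len(nrow(up))
  else up$rank <- integer(0)
  if (nrow(down)) down$rank <- seq_len(nrow(down))
  else down$rank <- integer(0)
  excluded <- data.frame(reaction_id = scores$reaction_id[!is.na(excl_reason)],
                         reason = excl_reason[!is.na(excl_reason)],
                         stringsAsFactors = FALSE)
  structure(list(up = up, down = down, excluded = excluded, config = config),
            class = "fseof_targets")
}

#' @export
print.fseof_targets <- function(x, ...) {
  cat("<fseof_targets> ", nrow(x$up), " up, ", nrow(x$down), " down, ",
      nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Gene-level scores
#'
#' Each gene inherits the extremal score among the scored reactions whose
#' gene rule contains it: the maximum for the up direction (`ACTIVATED`
#' dominating any numeric score) and the minimum for the down direction.
#' Genes appearing in no rule are omitted; withheld (direction-flip)
#' reaction scores do not contribute.
#'
#' @param model A `gem_model`.
#' @param scores A `fseof_scores` data frame.
#' @return Data frame: `gene`, `up_activated`, `up_score`, `down_score`,
#'   `n_reactions`, `reactions`.
#' @export
score_genes <- function(model, scores) {
  gmap <- lapply(scores$reaction_id,
                 function(rid) gpr_genes(model$reactions[[rid]]$gpr))
  genes <- sort(unique(unlist(gmap)))
  rows <- lapply(genes, function(g) {
    idx <- which(vapply(gmap, function(gs) g %in% gs, NA))
    sc <- scores$score[idx]
    act <- scores$activated[idx]
    num <- sc[!is.na(sc)]
    data.frame(gene = g,
               up_activated = any(act),
               up_score = if (any(act)) NA_real_ else if (length(num)) max(num) else NA_real_,
               down_score = if (length(num)) min(num) else NA_real_,
               n_reactions = length(idx),
               reactions = paste(scores$reaction_id[idx], collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Export a target table as TSV
#'
#' Columns: rank, reaction_id, genes, direction, score (`ACTIVATED` for
#' activated reactions), control_flux, production_flux_mean, and the
#' per-level fluxes. Deterministic: re-exporting an identical table yields
#' a byte-identical file; an empty table yields a header-only file.
#'
#' @param table A `fseof_targets`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_target_table <- function(table, path) {
  stopifnot(inherits(table, "fseof_targets"))
  levcols <- grep("^flux_f", names(table$up), value = TRUE)
  one <- function(d, direction) {
    if (nrow(d) == 0L) return(NULL)
    out <- data.frame(rank = d$rank, reaction_id = d$reaction_id,
                      genes = d$genes, direction = direction,
                      score = ifelse(d$activated, "ACTIVATED", fmt_num(d$score)),
                      control_flux = fmt_num(d$control_flux),
                      production_flux_mean = fmt_num(d$production_flux_mean),
                      stringsAsFactors = FALSE)
    for (cc in levcols) out[[cc]] <- fmt_num(d[[cc]])
    out
  }
  rows <- rbind(one(table$up, "up"), one(table$down, "down"))
  if (is.null(rows)) {
    rows <- data.frame(rank = integer(), reaction_id = character(),
                       genes = character(), direction = character(),
                       score = character(), control_flux = character(),
                       production_flux_mean = character(),
                       stringsAsFactors = FALSE)
    for (cc in levcols) rows[[cc]] <- character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Export the scan flux matrix as TSV
#'
#' @param scan A `fseof_scan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_scan_matrix <- function(scan, path) {
  m <- scan_matrix(scan)
  d <- data.frame(reaction_id = rownames(m), stringsAsFactors = FALSE)
  for (cc in colnames(m)) d[[cc]] <- fmt_num(m[, cc])
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
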