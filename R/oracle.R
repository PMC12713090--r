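# Independent brute-force scoring path, used to validate the main
# implementation on small models. Deliberately coded apart from the main
# path: a Python script (inst/python/fseof_oracle.py) with dense numpy
# matrices and scipy's HiGHS linprog backend recomputes the whole scan
# over a fine fraction grid; R only marshals the model and reads scores
# back.

#' Brute-force oracle scores
#'
#' Recomputes scan scores through an independently coded path: the model
#' is serialized to the JSON dialect and handed to a bundled Python script
#' that rebuilds the scan with dense matrices and the HiGHS linear
#' programming backend (`scipy.optimize.linprog`) on a fine fraction grid
#' (step `fine_step` across the configured range); the values at the
#' configured fractions feed the same scoring semantics as
#' [score_reactions()]. Only meant for validation on small models; refuses
#' models above `max_size` reactions.
#'
#' @param model A `gem_model` with at most `max_size` reactions.
#' @param config A [scan_config()].
#' @param fine_step Fine grid step (default 0.01).
#' @param max_size Size guard.
#' @param python Python interpreter to invoke.
#' @return Data frame `reaction_id`, `score`, `activated`, `control_flux`,
#'   `production_flux_mean`; attribute `envelope` holds the fine-grid
#'   (fraction, target max) curve and attribute `mu_max` the maximal
#'   biomass flux.
#' @export
oracle_scores <- function(model, config, fine_step = 0.01, max_size = 25,
                          python = "python") {
  if (length(model$reactions) > max_size)
    stop("oracle_scores is restricted to models with <= ", max_size,
         " reactions")
  stopifnot(inherits(config, "scan_config"))
  script <- system.file("python", "fseof_oracle.py", package = "fluxscan")
  if (!nzchar(script)) stop("bundled oracle script not found")

  mpath <- tempfile(fileext = ".json")
  jpath <- tempfile(fileext = ".json")
  opath <- tempfile(fileext = ".json")
  on.exit(unlink(c(mpath, jpath, opath)))
  write_model(model, mpath, "json")
  job <- list(model = jsonlite::read_json(mpath),
              biomass = config$biomass_reaction_id,
              target = config$target_reaction_id,
              fractions = config$fractions,
              fine_step = fine_step,
              activation_epsilon = config$activation_epsilon,
              aggregation = config$aggregation,
              use_pfba_for_control = config$use_pfba_for_control)
  jsonlite::write_json(job, jpath, auto_unbox = TRUE, digits = NA)
  out <- system2(python, c(script, jpath, opath), stdout = TRUE, stderr = TRUE)
  st <- attr(out, "status")
  if (!is.null(st) && st != 0)
    stop("oracle script failed: ", paste(out, collapse = "\n"))
  res <- jsonlite::read_json(opath)
  scores <- do.call(rbind, lapply(res$scores, function(s) {
    data.frame(reaction_id = s$reaction_id,
               score = if (is.null(s$score)) NA_real_ else s$score,
               activated = isTRUE(s$activated),
               control_flux = s$control_flux,
               production_flux_mean = s$production_flux_mean,
               stringsAsFactors = FALSE)
  }))
  env <- do.call(rbind, lapply(res$envelope, function(e)
    data.frame(fraction = e[[1]],
               target_max = if (is.null(e[[2]])) NA_real_ else e[[2]])))
  attr(scores, "envelope") <- env
  attr(scores, "mu_max") <- res$mu_max
  scores
}
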