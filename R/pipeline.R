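#' Run the end-to-end target-prediction pipeline
#'
#' Stages: read (or take) the model, graft modules, set the medium, run the
#' control and the enforced-objective scan, score and classify, score
#' genes, export tables, and optionally compare intervention scenarios.
#' Every artifact is written under `out_dir` together with a run manifest
#' (input checksums, config echo, package version, per-stage status and
#' wall time, output checksums). A stage failure is recorded with its cause
#' and downstream stages are skipped. Identical config and inputs produce
#' byte-identical target tables.
#'
#' @param config A list (or path to a YAML/JSON file) with entries:
#'   `model` (path) or `model_object` (a `gem_model`); optional
#'   `model_format`; optional `grafts` (list of lists with `module` =
#'   `"spinosad"`/`"ncm"` or a [pathway_module()], optional `granularity`,
#'   and `mapping` = `"bigg"`, `"toy_host"`, or a named vector); optional
#'   `medium` (named uptake map); `scan` (arguments for [scan_config()]);
#'   optional `scenarios`; `out_dir`.
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  if (is.null(config[["model"]]) && is.null(config[["model_object"]]))
    stop("config must name a model file or carry a model_object")
  if (!is.null(config[["model"]]) && !file.exists(config[["model"]]))
    stop("model file not found: ", config[["model"]])
  if (is.null(config$scan)) stop("config$scan is required")

  manifest <- list(
    tool = paste0("fluxscan ", as.character(utils::packageVersion("fluxscan"))),
    inputs = list(), config = config["scan"], stages = list(), outputs = list())
  if (!is.null(config[["model"]]))
    manifest$inputs$model <- list(path = config[["model"]],
                                  md5 = unname(tools::md5sum(config[["model"]])))

  failed <- FALSE
  stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       cause = conditionMessage(e))
      failed <<- TRUE
      NULL
    })
    if (!failed)
      manifest$stages[[name]] <<- list(
        status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  register <- function(name, path) {
    manifest$outputs[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
  }

  model <- stage("read", function() {
    if (!is.null(config[["model_object"]])) config[["model_object"]]
    else read_model(config[["model"]], config[["model_format"]] %||% "auto")
  })
  model <- stage("graft", function() {
    m <- model
    for (g in config$grafts %||% list()) {
      mod <- g$module
      if (is.character(mod))
        mod <- switch(mod,
                      spinosad = build_spinosad_module(g$granularity %||% "branch"),
                      ncm = build_ncm_module(),
                      stop("unknown module name: ", mod))
      mapping <- g$mapping %||% "bigg"
      if (is.character(mapping) && length(mapping) == 1L)
        mapping <- switch(mapping, bigg = bigg_mapping(mod),
                          toy_host = toy_host_mapping(),
                          stop("unknown mapping name: ", mapping))
      m <- graft_module(m, mod, mapping)
    }
    m
  }) %||% model
  model <- stage("medium", function() {
    if (is.null(config$medium)) model
    else set_medium(model, config$medium)
  }) %||% model
  if (!failed) manifest$inputs$model_checksum <- model_checksum(model)

  sc <- if (!failed) do.call(scan_config, config$scan) else NULL
  scan <- stage("scan", function() run_scan(model, sc))
  scores <- stage("score", function() score_reactions(scan))
  targets <- stage("classify", function() classify_targets(scores, model, sc))
  gene_tab <- stage("genes", function() score_genes(model, scores))
  stage("export", function() {
    tpath <- file.path(out_dir, "targets.tsv")
    export_target_table(targets, tpath); register("targets", tpath)
    mpath <- file.path(out_dir, "scan_matrix.tsv")
    export_scan_matrix(scan, mpath); register("scan_matrix", mpath)
    gpath <- file.path(out_dir, "gene_scores.tsv")
    gd <- gene_tab
    for (cc in c("up_score", "down_score")) gd[[cc]] <- fmt_num(gd[[cc]])
    con <- file(gpath, open = "wb")
    utils::write.table(gd, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
    close(con)
    register("gene_scores", gpath)
    invisible(NULL)
  })
  if (!is.null(config$scenarios)) {
    stage("scenarios", function() {
      res <- compare_scenarios(model, config$scenarios$list,
                               config$scenarios$target %||% sc$target_reaction_id,
                               config$scenarios$substrate,
                               config$scenarios$biomass_floor_fraction %||% 0.1)
      spath <- file.path(out_dir, "scenarios.tsv")
      rd <- res
      for (cc in c("max_target_flux", "substrate_uptake",
                   "yield_per_substrate", "delta_vs_base"))
        rd[[cc]] <- fmt_num(rd[[cc]])
      con <- file(spath, open = "wb")
      utils::write.table(rd, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, eol = "\n")
      close(con)
      register("scenarios", spath)
      res
    })
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}
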