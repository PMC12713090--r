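# Shared helpers for the suite.

t1_config <- function(...) scan_config("R_bio", "EX_p", ...)

# Assert an optimal flux distribution respects mass balance and bounds.
expect_feasible <- function(model, dist, tol = 1e-6) {
  expect_identical(dist$status, "optimal")
  S <- stoichiometric_matrix(model)
  expect_lt(max(abs(as.numeric(S %*% dist$fluxes[colnames(S)]))), tol)
  b <- rxn_bounds(model)
  v <- dist$fluxes[rownames(b)]
  expect_true(all(v >= b[, "lb"] - tol))
  expect_true(all(v <= b[, "ub"] + tol))
}

# Compare the main scoring path with the scipy-based oracle on one model.
score_gap_vs_oracle <- function(model, config, fine_step = 0.01) {
  s <- score_reactions(run_scan(model, config))
  o <- oracle_scores(model, config, fine_step = fine_step)
  m <- merge(s[, c("reaction_id", "score", "activated")],
             o[, c("reaction_id", "score", "activated")],
             by = "reaction_id")
  stopifnot(identical(m$activated.x, m$activated.y),
            identical(is.na(m$score.x), is.na(m$score.y)))
  gap <- max(abs(m$score.x - m$score.y), na.rm = TRUE)
  if (!is.finite(gap)) gap <- 0
  gap
}

# A hand-built fseof_scores frame for classification unit tests.
fake_scores <- function(tab, config) {
  df <- data.frame(reaction_id = tab$reaction_id,
                   score = tab$score,
                   activated = tab$activated,
                   control_flux = tab$control_flux,
                   production_flux_mean = tab$production_flux_mean,
                   direction_consistent = tab$direction_consistent %||% TRUE,
                   reason = tab$reason,
                   stringsAsFactors = FALSE)
  attr(df, "config") <- config
  class(df) <- c("fseof_scores", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
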