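# The package's LP core: a dense two-phase primal simplex with Bland's
# rule. Written in-package because the only LP routine shipped with the
# installed R stack (boot::simplex) mis-pivots when phase 1 ends with a
# degenerate artificial basis, which steady-state flux polytopes with
# closed cycles routinely produce. Bland's rule makes the solver
# cycle-free and fully deterministic (fixed variable order, no presolve
# randomness), which the scan's flux-ratio scores require.

# Solve min c.x  s.t.  A x = b (b >= 0 after internal sign flips), x >= 0.
# Returns list(status = "optimal"|"infeasible"|"unbounded", x).
fs_simplex <- function(A, b, cc, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  run <- function(Tab, basis, cost, ncols) {
    repeat {
      cb <- cost[basis]
      red <- cost[seq_len(ncols)] -
        as.numeric(crossprod(cb, Tab[, seq_len(ncols), drop = FALSE]))
      enter <- which(red < -tol)
      if (!length(enter)) return(list(Tab = Tab, basis = basis, status = "optimal"))
      e <- enter[1L]                          # Bland: smallest index enters
      col <- Tab[, e]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- Tab[pos, ncol(Tab)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol * max(1, abs(rmin))]
      r <- cand[which.min(basis[cand])]       # Bland: smallest basic index leaves
      Tab[r, ] <- Tab[r, ] / Tab[r, e]
      other <- setdiff(seq_len(nrow(Tab)), r)
      Tab[other, ] <- Tab[other, ] - outer(Tab[other, e], Tab[r, ])
      basis[r] <- e
      Tab[abs(Tab) < 1e-13] <- 0
    }
  }

  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  r1 <- run(Tab, basis, cost1, n)             # artificials never re-enter
  if (r1$status != "optimal") return(list(status = "infeasible", x = NULL))
  Tab <- r1$Tab; basis <- r1$basis
  if (sum(cost1[basis] * Tab[, ncol(Tab)]) > 1e-7)
    return(list(status = "infeasible", x = NULL))
  # drive remaining artificials out of the basis; rows that cannot pivot
  # are redundant constraints and are dropped
  for (r in which(basis > n)) {
    piv <- which(abs(Tab[r, seq_len(n)]) > tol)
    if (length(piv)) {
      e <- piv[1L]
      Tab[r, ] <- Tab[r, ] / Tab[r, e]
      other <- setdiff(seq_len(nrow(Tab)), r)
      Tab[other, ] <- Tab[other, ] - outer(Tab[other, e], Tab[r, ])
      basis[r] <- e
    }
  }
  keep <- basis <= n
  Tab <- Tab[keep, c(seq_len(n), ncol(Tab)), drop = FALSE]
  basis <- basis[keep]
  r2 <- run(Tab, basis, cc, n)
  if (r2$status != "optimal") return(list(status = r2$status, x = NULL))
  x <- numeric(n)
  x[r2$basis] <- r2$Tab[, ncol(r2$Tab)]
  list(status = "optimal", x = x)
}

# Bounded-variable LP over a flux polytope:
#   optimize obj.v  s.t.  S v = rhs, lb <= v <= ub.
# Variables whose bound interval is (numerically) a point are eliminated
# before solving; infinite bounds are boxed at +/-`big` and a solution
# pressing an artificial box with nonzero objective weight is reported
# unbounded.
fs_lp <- function(S, lb, ub, obj, maximize = TRUE, rhs = NULL, big = 1e6) {
  n <- length(lb)
  S <- as.matrix(S)
  if (is.null(rhs)) rhs <- numeric(nrow(S))
  inf_lo <- !is.finite(lb); inf_hi <- !is.finite(ub)
  lb2 <- ifelse(inf_lo, -big, lb)
  ub2 <- ifelse(inf_hi, big, ub)
  if (any(lb2 > ub2)) return(list(status = "infeasible", v = NULL, value = NA_real_))

  fixed <- (ub2 - lb2) <= 1e-8 * pmax(1, abs(lb2))
  vfix <- (lb2 + ub2) / 2
  free <- which(!fixed)
  b_eq <- rhs - if (any(fixed)) as.numeric(S[, fixed, drop = FALSE] %*% vfix[fixed]) else 0
  if (!length(free)) {
    v <- vfix
    feas <- max(abs(as.numeric(S %*% v) - rhs)) <= 1e-6
    return(if (feas) list(status = "optimal", v = v, value = sum(obj * v))
           else list(status = "infeasible", v = NULL, value = NA_real_))
  }
  Sf <- S[, free, drop = FALSE]
  lf <- lb2[free]; uf <- ub2[free]
  rng <- uf - lf
  nf <- length(free)
  # standard form: x = v_free - lf >= 0; slack rows x_i + s_i = rng_i
  A <- rbind(cbind(Sf, matrix(0, nrow(Sf), nf)),
             cbind(diag(nf), diag(nf)))
  b <- c(b_eq - as.numeric(Sf %*% lf), rng)
  cc <- c(if (maximize) -obj[free] else obj[free], rep(0, nf))
  res <- fs_simplex(A, b, cc)
  if (res$status != "optimal")
    return(list(status = res$status, v = NULL, value = NA_real_))
  v <- vfix
  v[free] <- res$x[seq_len(nf)] + lf
  hit <- (inf_hi & v > big - 1e-3) | (inf_lo & v < -big + 1e-3)
  if (any(hit & obj != 0))
    return(list(status = "unbounded", v = v, value = sum(obj * v)))
  list(status = "optimal", v = v, value = sum(obj * v))
}
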