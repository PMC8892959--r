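## Dense two-phase primal simplex for the small equality-form LPs this
## package needs: per-gene abundance bounds and the path-enumeration oracle.
##   min / max  c'x   s.t.  A x = b,  x >= 0
## Bland's rule throughout (no cycling); problems are tiny (tens of
## variables), so the full-tableau method is both simple and fast enough.

## One simplex phase on tableau `Tab` = [columns | rhs] with cost vector
## `cost` over the columns. Minimizes. Returns the final tableau, basis and
## objective, with status "optimal" or "unbounded".
.simplex_phase <- function(Tab, basis, cost, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(Tab)
  nc <- ncol(Tab) - 1L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex iteration limit exceeded")
    cB <- cost[basis]
    red <- as.vector(cB %*% Tab[, seq_len(nc), drop = FALSE]) - cost
    red[basis] <- 0
    enter_candidates <- which(red > tol)
    if (!length(enter_candidates)) {
      obj <- sum(cB * Tab[, nc + 1L])
      return(list(Tab = Tab, basis = basis, objective = obj,
                  status = "optimal"))
    }
    j <- enter_candidates[1L]  # Bland: smallest index
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(Tab = Tab, basis = basis, objective = -Inf,
                  status = "unbounded"))
    }
    theta <- Tab[pos, nc + 1L] / col[pos]
    tmin <- min(theta)
    ties <- pos[theta <= tmin + tol * max(1, abs(tmin))]
    i <- ties[which.min(basis[ties])]  # Bland on leaving variable
    ## pivot on (i, j)
    Tab[i, ] <- Tab[i, ] / Tab[i, j]
    others <- setdiff(seq_len(m), i)
    if (length(others)) {
      Tab[others, ] <- Tab[others, , drop = FALSE] -
        outer(Tab[others, j], Tab[i, ])
    }
    basis[i] <- j
  }
}

## Solve min/max c'x s.t. Ax = b, x >= 0.
## Returns list(status = "optimal" | "infeasible" | "unbounded",
##              x = primal solution, objective).
.lp_solve <- function(A, b, cvec, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A)
  n <- ncol(A)
  b <- as.numeric(b)
  stopifnot(length(b) == m, length(cvec) == n)
  ## normalise to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  ## drop rows that are identically zero (or declare infeasibility)
  scale <- max(1, abs(b), abs(A))
  zr <- apply(abs(A), 1L, max) <= tol * scale
  if (any(zr & b > 1e-7 * scale)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  A <- A[!zr, , drop = FALSE]
  b <- b[!zr]
  m <- nrow(A)
  if (m == 0L) {
    ## any x >= 0 is feasible; optimum at x = 0 unless improving direction
    improving <- if (maximize) any(cvec > tol) else any(cvec < -tol)
    if (improving) {
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    }
    return(list(status = "optimal", x = numeric(n), objective = 0))
  }
  ## Phase 1: artificials
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(numeric(n), rep(1, m))
  p1 <- .simplex_phase(Tab, basis, cost1, tol)
  if (p1$status != "optimal" || p1$objective > 1e-7 * scale) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  Tab <- p1$Tab
  basis <- p1$basis
  ## drive artificials out of the basis (they sit at level ~0)
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] > n) {
      piv <- which(abs(Tab[i, seq_len(n)]) > tol)
      if (length(piv)) {
        j <- piv[1L]
        Tab[i, ] <- Tab[i, ] / Tab[i, j]
        others <- setdiff(seq_len(nrow(Tab)), i)
        Tab[others, ] <- Tab[others, , drop = FALSE] -
          outer(Tab[others, j], Tab[i, ])
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)  # redundant constraint
      }
    }
  }
  if (length(drop_rows)) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  ## Phase 2 on the original columns only
  Tab2 <- Tab[, c(seq_len(n), ncol(Tab)), drop = FALSE]
  cost2 <- if (maximize) -as.numeric(cvec) else as.numeric(cvec)
  p2 <- .simplex_phase(Tab2, basis, cost2, tol)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  x <- numeric(n)
  rhs <- p2$Tab[, n + 1L]
  inb <- p2$basis <= n
  x[p2$basis[inb]] <- rhs[inb]
  x[x < 0 & x > -1e-9] <- 0
  obj <- sum(cvec * x)
  list(status = "optimal", x = x, objective = obj)
}

## Feasibility of Ax = b, x >= 0 (phase 1 only).
.lp_feasible <- function(A, b, tol = 1e-9) {
  n <- ncol(as.matrix(A))
  res <- .lp_solve(A, b, numeric(n), maximize = FALSE, tol = tol)
  res$status == "optimal"
}

## min and max of x[j] subject to Ax = b, x >= 0. Returns c(lo, hi) or
## stops if infeasible/unbounded (callers guarantee boundedness).
.lp_bounds <- function(A, b, j, tol = 1e-9) {
  n <- ncol(as.matrix(A))
  cvec <- numeric(n)
  cvec[j] <- 1
  lo <- .lp_solve(A, b, cvec, maximize = FALSE, tol = tol)
  hi <- .lp_solve(A, b, cvec, maximize = TRUE, tol = tol)
  if (lo$status != "optimal" || hi$status != "optimal") {
    stop("internal error: variable bound LP returned status ",
         lo$status, "/", hi$status)
  }
  c(lo$objective, hi$objective)
}
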