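# Dense two-phase simplex for the small linear programs arising in
# constraint-based flux analysis (tens of variables, tens of constraints).
# Problems are stated as
#     min  c'x   s.t.  Aeq x = beq,  Aineq x <= bineq,  lower <= x <= upper
# and converted to computational standard form (min c'x, Ax = b, x >= 0)
# before pivoting.  Bland's rule is switched on after a pivot budget to
# guarantee termination under degeneracy.

#' Solve a (small, dense) linear program
#'
#' @param obj numeric objective coefficients (minimised unless `maximize`).
#' @param Aeq,beq equality constraints `Aeq x = beq` (may be `NULL`).
#' @param Aineq,bineq inequality constraints `Aineq x <= bineq` (may be `NULL`).
#' @param lower,upper variable bounds, recycled to the number of variables;
#'   use `-Inf`/`Inf` for unbounded directions.
#' @param maximize maximise instead of minimise.
#' @param tol feasibility/pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), solution `x`, objective `objval`, and
#'   `kkt_residual`, the largest violation among primal feasibility and
#'   reduced-cost (complementarity) conditions at the reported solution.
#' @keywords internal
#' @noRd
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                     lower = 0, upper = Inf, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(lower > upper)) stop("lp_solve: inconsistent bounds")
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  if (is.null(Aeq))   { Aeq   <- matrix(0, 0, n); beq   <- numeric(0) }
  if (is.null(Aineq)) { Aineq <- matrix(0, 0, n); bineq <- numeric(0) }
  Aeq <- matrix(as.numeric(Aeq), ncol = n)
  Aineq <- matrix(as.numeric(Aineq), ncol = n)

  ## --- translate variables to standard form -----------------------------
  ## Each original variable becomes one or two nonnegative columns; finite
  ## upper bounds after shifting become extra equality rows with a slack.
  map <- vector("list", n)      # per variable: list(cols, signs, shift)
  cols <- list(); csf <- numeric(0)
  ub_rows <- list()             # list(col_index, bound) filled after split
  k <- 0L
  for (j in seq_len(n)) {
    lj <- lower[j]; uj <- upper[j]
    if (is.finite(lj)) {
      k <- k + 1L
      map[[j]] <- list(cols = k, signs = 1, shift = lj)
      csf <- c(csf, cc[j])
      if (is.finite(uj)) ub_rows[[length(ub_rows) + 1L]] <- c(k, uj - lj)
    } else if (is.finite(uj)) {           # (-Inf, u]: x = u - y, y >= 0
      k <- k + 1L
      map[[j]] <- list(cols = k, signs = -1, shift = uj)
      csf <- c(csf, -cc[j])
    } else {                              # free: x = y+ - y-
      map[[j]] <- list(cols = c(k + 1L, k + 2L), signs = c(1, -1), shift = 0)
      csf <- c(csf, cc[j], -cc[j])
      k <- k + 2L
    }
  }
  nsf <- k

  expand_rows <- function(A) {
    if (nrow(A) == 0L) return(matrix(0, 0, nsf))
    M <- matrix(0, nrow(A), nsf)
    for (j in seq_len(n)) {
      mj <- map[[j]]
      for (i in seq_along(mj$cols)) M[, mj$cols[i]] <- M[, mj$cols[i]] + A[, j] * mj$signs[i]
    }
    M
  }
  shift <- vapply(seq_len(n), function(j) map[[j]]$shift, numeric(1))
  beq2 <- beq - as.numeric(Aeq %*% shift)
  bin2 <- bineq - as.numeric(Aineq %*% shift)
  E <- expand_rows(Aeq); G <- expand_rows(Aineq)

  ## inequality slacks
  ns <- nrow(G)
  if (ns > 0L) {
    E <- rbind(E, G)
    E <- cbind(E, rbind(matrix(0, length(beq2), ns), diag(ns)))
    beq2 <- c(beq2, bin2)
    csf <- c(csf, rep(0, ns))
  }
  ## upper-bound rows
  nu <- length(ub_rows)
  if (nu > 0L) {
    U <- matrix(0, nu, ncol(E)); ub <- numeric(nu)
    for (i in seq_len(nu)) { U[i, ub_rows[[i]][1]] <- 1; ub[i] <- ub_rows[[i]][2] }
    E <- rbind(E, U)
    E <- cbind(E, rbind(matrix(0, nrow(E) - nu, nu), diag(nu)))
    beq2 <- c(beq2, ub)
    csf <- c(csf, rep(0, nu))
  }

  res <- .simplex_standard(csf, E, beq2, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(NA_real_, n), objval = NA_real_,
                kkt_residual = NA_real_))
  }
  xsf <- res$x
  x <- numeric(n)
  for (j in seq_len(n)) {
    mj <- map[[j]]
    x[j] <- mj$shift + sum(mj$signs * xsf[mj$cols])
  }
  objval <- sum(cc * x)

  ## KKT / feasibility certificate on the original problem
  prim <- 0
  if (length(beq)) prim <- max(prim, max(abs(Aeq %*% x - beq)))
  if (length(bineq)) prim <- max(prim, max(c(0, Aineq %*% x - bineq)))
  prim <- max(prim, max(c(0, lower - x)), max(c(0, x - upper)))
  kkt <- max(prim, res$dual_residual)

  list(status = "optimal", x = x,
       objval = if (maximize) -objval else objval,
       kkt_residual = kkt)
}

## Tableau simplex for  min c'x  s.t.  A x = b, x >= 0  (b made nonnegative).
## Returns status, x, and the worst negative reduced cost at termination
## (dual_residual) as an optimality certificate.
.simplex_standard <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {  # only bounds: optimum at x = 0 when c >= 0, else unbounded
    if (all(cc >= -tol)) {
      return(list(status = "optimal", x = numeric(n), dual_residual = max(c(0, -cc))))
    }
    return(list(status = "unbounded", x = rep(NA_real_, n), dual_residual = NA_real_))
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  ## scale rows to unit max magnitude for numerical stability
  rs <- pmax(apply(abs(A), 1, max), 1e-12)
  A <- A / rs; b <- b / rs

  Afull <- cbind(A, diag(m))          # artificial columns n+1 .. n+m
  basis <- n + seq_len(m)
  Tb <- cbind(Afull, b)               # m x (n+m+1)

  run_phase <- function(Tb, basis, cost, allowed, itmax) {
    m <- nrow(Tb); N <- ncol(Tb) - 1L
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > itmax) return(list(Tb = Tb, basis = basis, status = "iteration_limit"))
      cb <- cost[basis]
      y <- crossprod(Tb[, seq_len(N), drop = FALSE], cb)   # N x 1
      red <- cost[seq_len(N)] - as.numeric(y)
      red[!allowed] <- Inf
      red[basis] <- Inf
      bland <- it > 4L * (m + N)
      cand <- which(red < -tol)
      if (!length(cand)) {
        rr <- red[is.finite(red)]
        return(list(Tb = Tb, basis = basis, status = "optimal",
                    dual_residual = max(c(0, -rr))))
      }
      q <- if (bland) cand[1] else cand[which.min(red[cand])]
      col <- Tb[, q]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[pos, N + 1L] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      p <- if (length(ties) > 1L) ties[which.min(basis[ties])] else ties
      ## pivot on (p, q)
      piv <- Tb[p, q]
      Tb[p, ] <- Tb[p, ] / piv
      other <- setdiff(seq_len(m), p)
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, q], Tb[p, ])
      basis[p] <- q
    }
  }

  Ntot <- n + m
  itmax <- 200L + 60L * Ntot
  ## phase 1
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(Tb, basis, c1, allowed = rep(TRUE, Ntot), itmax = itmax)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "infeasible" else ph1$status,
                x = rep(NA_real_, n), dual_residual = NA_real_))
  }
  Tb <- ph1$Tb; basis <- ph1$basis
  p1obj <- sum(Tb[basis > n, Ntot + 1L])
  if (p1obj > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), dual_residual = NA_real_))
  }
  ## drive remaining artificials (basic at zero) out of the basis
  for (p in which(basis > n)) {
    row <- Tb[p, seq_len(n)]
    q <- which(abs(row) > 1e-7)
    if (length(q)) {
      q <- q[1]
      piv <- Tb[p, q]
      Tb[p, ] <- Tb[p, ] / piv
      other <- setdiff(seq_len(nrow(Tb)), p)
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, q], Tb[p, ])
      basis[p] <- q
    }
    ## else: redundant row; keep (harmless) with artificial pinned at zero
  }
  ## phase 2: forbid artificial columns
  allowed <- c(rep(TRUE, n), rep(FALSE, m))
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(Tb, basis, c2, allowed = allowed, itmax = itmax)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = rep(NA_real_, n), dual_residual = NA_real_))
  }
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- Tb[inb, n + nrow(Tb) + 1L]
  x[x < 0 & x > -1e-9] <- 0
  list(status = "optimal", x = x, dual_residual = ph2$dual_residual)
}
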