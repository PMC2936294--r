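# Variance-weighted least-squares consistency.
#
# The classical gross-error index: minimise (w - Cv)' F^{-1} (w - Cv) over
# steady-state flux vectors v, with F diagonal from a relative standard
# deviation per measurement.  Under equality constraints only, the optimal
# residual follows a chi-square distribution; the inequality
# (irreversibility) constraints used here invalidate that distribution, so
# the residual is reported as a raw index, with the chi-square reference
# quantile attached for orientation only when no inequality is active.

#' Weighted least-squares consistency residual
#'
#' @param model a `metabolic_model`.
#' @param values named numeric measurements (see
#'   [possibilistic_measurements()] for the naming convention).
#' @param rel_sd relative standard deviation assigned to each measurement
#'   (default 10 %).
#' @param zero_floor scale floor for zero-valued measurements (shares its
#'   default with the possibilistic module for comparability).
#' @return list with `phi` (the minimised variance-weighted residual),
#'   `v_hat` (the fitted flux vector), `active_inequalities` (number of
#'   irreversibility constraints active at the optimum) and `chisq_ref`
#'   (0.95 chi-square quantile at `m - measurement_rank` ... degrees of
#'   freedom, `NA` when inequalities are active and the reference is
#'   invalid).
#' @export
wls_residual <- function(model, values, rel_sd = 0.10, zero_floor = 0.05) {
  stopifnot(inherits(model, "metabolic_model"), length(values) > 0)
  meas <- possibilistic_measurements(model, values, zero_floor = zero_floor)
  C <- attr(meas, "C")
  w <- meas$w
  s <- rel_sd * pmax(abs(w), zero_floor)
  if (any(s <= 0)) stop("variance flooring failed; rel_sd and zero_floor must be positive")

  ## reduce to the nullspace of N: v = B z
  n <- length(model$reaction_ids)
  B <- nullspace_basis(model$N, n)
  G <- B[!model$reversible, , drop = FALSE]     # irreversibility: G z >= 0
  Cw <- C / s                                    # rows scaled by 1/sd
  ww <- w / s
  M <- Cw %*% B
  D <- 2 * crossprod(M)
  ## ridge regularises directions of the nullspace that the measurements do
  ## not see (phi is flat along them); magnitude keeps the distortion far
  ## below reporting precision
  eps <- 1e-8 * max(diag(D), 1)
  diag(D) <- diag(D) + eps
  d <- 2 * crossprod(M, ww)
  sol <- quadprog::solve.QP(Dmat = D, dvec = d, Amat = t(G),
                            bvec = rep(0, nrow(G)), meq = 0)
  z <- sol$solution
  v_hat <- drop(B %*% z)
  names(v_hat) <- model$reaction_ids
  resid <- ww - drop(M %*% z)
  phi <- sum(resid^2)
  act <- sum(abs(G %*% z) < 1e-7 & rowSums(abs(G)) > 0)
  mrank <- mat_rank(rbind(model$N, C)) - mat_rank(model$N)
  chisq_ref <- if (act == 0L && nrow(meas) > mrank) {
    stats::qchisq(0.95, df = nrow(meas) - mrank)
  } else NA_real_
  list(phi = phi, v_hat = v_hat, active_inequalities = act,
       chisq_ref = chisq_ref)
}

## Orthonormal basis of the nullspace of A (n columns).
nullspace_basis <- function(A, n) {
  if (nrow(A) == 0L) return(diag(n))
  sv <- svd(A, nu = 0, nv = n)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r >= n) return(matrix(0, n, 0))
  sv$v[, (r + 1L):n, drop = FALSE]
}
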