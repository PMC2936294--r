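# Independent oracles used across the suite.  These deliberately avoid the
# implementation paths they check: elementary modes come from exhaustive
# support-subset enumeration, linear programs from brute-force vertex
# enumeration.

## Exhaustive elementary-mode oracle: a support set T is an elementary mode
## iff the nullspace of N restricted to T is one-dimensional, its basis
## vector has no zero on T, and the signs can be oriented to satisfy the
## irreversibility constraints.  Feasible only for small n.
oracle_ems <- function(model) {
  N <- model$N; n <- ncol(N); irr <- !model$reversible
  out <- list()
  for (size in seq_len(n)) {
    for (Tset in utils::combn(n, size, simplify = FALSE)) {
      K <- N[, Tset, drop = FALSE]
      sv <- svd(K, nv = length(Tset))
      r <- sum(sv$d > 1e-10)
      if (length(Tset) - r != 1L) next
      v <- sv$v[, length(Tset)]
      if (any(abs(v) < 1e-8)) next
      full <- numeric(n); full[Tset] <- v
      iT <- irr & (seq_len(n) %in% Tset)
      if (any(iT)) {
        full <- full * sign(full[which(iT)[1]])
        if (any(full[iT] < -1e-9)) next
      } else {
        j <- which(abs(full) > 1e-9)[1]
        if (full[j] < 0) full <- -full
      }
      out[[length(out) + 1L]] <- full / max(abs(full))
    }
  }
  if (!length(out)) return(matrix(0, 0, n))
  M <- do.call(rbind, out)
  M[!duplicated(apply(M, 1, function(v) paste(round(v, 8), collapse = ","))), ,
    drop = FALSE]
}

## Canonical fingerprint of a mode set (scale to max |entry| = 1, sort).
canon_modes <- function(M) {
  if (!nrow(M)) return(character(0))
  unname(sort(apply(M, 1, function(v) {
    v <- v / max(abs(v))
    v[abs(v) < 1e-9] <- 0
    paste(round(v, 7), collapse = ",")
  })))
}

## Brute-force LP minimiser over {Aineq x <= b, lower <= x <= upper} by
## enumerating candidate vertices; valid for bounded feasible sets.
brute_lp <- function(obj, Aineq, bineq, lower, upper) {
  n <- length(obj)
  A <- rbind(Aineq, diag(n), -diag(n))
  b <- c(bineq, upper, -lower)
  best <- Inf
  for (S in utils::combn(nrow(A), n, simplify = FALSE)) {
    M <- A[S, , drop = FALSE]
    if (abs(det(M)) < 1e-9) next
    x <- tryCatch(solve(M, b[S]), error = function(e) NULL)
    if (is.null(x)) next
    if (all(A %*% x <= b + 1e-8)) best <- min(best, sum(obj * x))
  }
  best
}

## Random small connected-ish stoichiometric toy network.
random_toy_model <- function(n_met, n_rxn, p_rev = 0.35) {
  repeat {
    S <- matrix(sample(c(-1, 0, 0, 1), n_met * n_rxn, replace = TRUE),
                n_met, n_rxn)
    if (all(colSums(S != 0) > 0)) break
  }
  metabolic_model(S, reversible = stats::runif(n_rxn) < p_rev)
}

## Three-reaction chain ->A->B-> with A, B internal.
chain_model <- function() {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("v1", "v2", "v3")))
  ex <- data.frame(quantity = character(0), metabolite = character(0),
                   direction = character(0), stringsAsFactors = FALSE)
  metabolic_model(S, reversible = c(FALSE, FALSE, FALSE), exchange_map = ex)
}

## Chain with external substrate/product rows kept in S so exchange
## functionals exist: Sx -> A -> Px.
chain_model_exchange <- function() {
  S <- matrix(c(-1, 0,
                1, -1,
                0, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("Sx", "A", "Px"), c("up", "out")))
  metabolic_model(S, reversible = c(FALSE, FALSE),
                  internal = c(FALSE, TRUE, FALSE),
                  carbons = c(1, 1, 1),
                  exchange_map = data.frame(quantity = c("substrate", "product"),
                                            metabolite = c("Sx", "Px"),
                                            direction = c("uptake", "production"),
                                            stringsAsFactors = FALSE))
}

pichia <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pichia_model()
    cache
  }
})

pichia_ems <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- enumerate_ems(pichia())
    cache
  }
})

scenarios_tab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_scenarios()
    cache
  }
})
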