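# Possibilistic metabolic flux analysis.
#
# Each measurement w_m of a flux (or of a linear functional of the flux
# vector, such as a gas-exchange rate) is relaxed into
#     w_m = v_m + eps1 - mu1 + eps2 - mu2,
#     eps1, mu1 >= 0,  0 <= eps2 <= eps2_max,  0 <= mu2 <= mu2_max
# with a linear cost J = sum(alpha * eps1 + beta * mu1).  A candidate flux
# state has possibility pi = exp(-J); deviations inside the [-eps2_max,
# mu2_max] band are fully possible (pi = 1) and larger deviations decay
# exponentially at rates alpha (above) and beta (below).  Consistency
# between model and data is the possibility of the best state, found by LP.

#' Shape a possibilistic measurement
#'
#' Default shaping: full possibility within `full_band` (±5 %) of the
#' measured value, and possibility `ref_possibility` (0.1) at `ref_band`
#' (±20 %) deviation, giving slope weights
#' `alpha = beta = -log(ref_possibility) / ((ref_band - full_band) * s)`
#' with `s = max(|w|, zero_floor)`.  The floor keeps zero-valued
#' measurements (e.g. an ethanol rate of 0) informative but bounded.
#'
#' @param w measured value (model flux units).
#' @param full_band half-width (fraction of `s`) of the fully possible band.
#' @param ref_band deviation (fraction of `s`) assigned `ref_possibility`.
#' @param ref_possibility possibility at `ref_band` deviation, in (0,1).
#' @param zero_floor scale floor (flux units) for near-zero measurements.
#' @return list with `w`, `scale`, `eps2_max`, `mu2_max`, `alpha`, `beta`.
#' @export
#' @examples
#' m <- shape_measurement(1.0)
#' measurement_possibility(m, 1.20)   # 0.1
#' measurement_possibility(m, 1.095)  # 0.5
shape_measurement <- function(w, full_band = 0.05, ref_band = 0.20,
                              ref_possibility = 0.1, zero_floor = 0.05) {
  if (full_band < 0 || ref_band < 0) stop("bands must be nonnegative")
  if (!(full_band < ref_band)) stop("full_band must be smaller than ref_band")
  if (!(ref_possibility > 0 && ref_possibility < 1)) {
    stop("ref_possibility must lie in (0, 1)")
  }
  s <- max(abs(w), zero_floor)
  slope <- -log(ref_possibility) / ((ref_band - full_band) * s)
  list(w = w, scale = s, eps2_max = full_band * s, mu2_max = full_band * s,
       alpha = slope, beta = slope)
}

#' Possibility of a single measured quantity taking a given value
#'
#' @param m a shaped measurement from [shape_measurement()].
#' @param value candidate true value of the measured quantity.
#' @return possibility in (0, 1].
#' @export
measurement_possibility <- function(m, value) {
  d <- value - m$w
  excess <- if (d >= 0) max(0, d - m$mu2_max) * m$beta else
    max(0, -d - m$eps2_max) * m$alpha
  exp(-excess)
}

#' Build a possibilistic measurement set for a model
#'
#' @param model a `metabolic_model`.
#' @param values named numeric vector; names are either quantities of the
#'   model's exchange map (`"glucose"`, `"biomass"`, ...) or reaction ids,
#'   values are the measured rates in model units (uptakes positive).
#' @param full_band,ref_band,ref_possibility,zero_floor see
#'   [shape_measurement()].
#' @return object of class `measurement_set`: data frame with one row per
#'   measurement (`quantity`, `w`, `scale`, `eps2_max`, `mu2_max`, `alpha`,
#'   `beta`) and the functional matrix as attribute `C` (rows map flux
#'   vectors to measured quantities).
#' @export
possibilistic_measurements <- function(model, values, full_band = 0.05,
                                       ref_band = 0.20, ref_possibility = 0.1,
                                       zero_floor = 0.05) {
  stopifnot(inherits(model, "metabolic_model"), length(values) > 0,
            !is.null(names(values)))
  n <- length(model$reaction_ids)
  C <- matrix(0, length(values), n,
              dimnames = list(names(values), model$reaction_ids))
  for (i in seq_along(values)) {
    nm <- names(values)[i]
    if (nm %in% model$exchange_map$quantity) {
      C[i, ] <- exchange_functionals(model, nm)
    } else if (nm %in% model$reaction_ids) {
      C[i, nm] <- 1
    } else stop("measurement '", nm, "' is neither an exchange quantity nor a reaction id")
  }
  rows <- lapply(values, shape_measurement, full_band = full_band,
                 ref_band = ref_band, ref_possibility = ref_possibility,
                 zero_floor = zero_floor)
  df <- data.frame(quantity = names(values),
                   w = vapply(rows, `[[`, 0, "w"),
                   scale = vapply(rows, `[[`, 0, "scale"),
                   eps2_max = vapply(rows, `[[`, 0, "eps2_max"),
                   mu2_max = vapply(rows, `[[`, 0, "mu2_max"),
                   alpha = vapply(rows, `[[`, 0, "alpha"),
                   beta = vapply(rows, `[[`, 0, "beta"),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(df, C = C, class = c("measurement_set", "data.frame"))
}

## Assemble the LP pieces shared by all possibilistic computations.
## Variable layout: [v (n), eps1 (m), mu1 (m), eps2 (m), mu2 (m)].
.pmfa_lp_parts <- function(model, meas) {
  C <- attr(meas, "C")
  n <- length(model$reaction_ids); m <- nrow(meas)
  nv <- n + 4L * m
  Nrows <- nrow(model$N)
  Aeq <- matrix(0, Nrows + m, nv)
  if (Nrows) Aeq[seq_len(Nrows), seq_len(n)] <- model$N
  beq <- c(rep(0, Nrows), meas$w)
  for (k in seq_len(m)) {
    r <- Nrows + k
    Aeq[r, seq_len(n)] <- C[k, ]
    Aeq[r, n + k] <- 1            # eps1
    Aeq[r, n + m + k] <- -1       # mu1
    Aeq[r, n + 2L * m + k] <- 1   # eps2
    Aeq[r, n + 3L * m + k] <- -1  # mu2
  }
  lower <- c(ifelse(model$reversible, -Inf, 0), rep(0, 4L * m))
  upper <- c(rep(Inf, n + 2L * m), meas$eps2_max, meas$mu2_max)
  cost <- c(rep(0, n), meas$alpha, meas$beta, rep(0, 2L * m))
  list(Aeq = Aeq, beq = beq, lower = lower, upper = upper, cost = cost,
       n = n, m = m)
}

#' Maximum-possibility flux state and consistency degree
#'
#' Solves the LP minimising the possibilistic cost J subject to the model
#' constraints (steady state + irreversibility) and the relaxed measurement
#' constraints; returns the most possible flux vector and its possibility
#' `pi = exp(-J)`, the degree of consistency between model and data
#' (1 = a flux state exists within every measurement's fully possible band).
#'
#' @param model a `metabolic_model`.
#' @param meas a `measurement_set`.
#' @return list with `pi`, `J_min`, `v_mp` (named flux vector), `status`.
#' @export
max_possibility <- function(model, meas) {
  p <- .pmfa_lp_parts(model, meas)
  r <- lp_solve(p$cost, Aeq = p$Aeq, beq = p$beq, lower = p$lower, upper = p$upper)
  if (r$status != "optimal") {
    stop("possibilistic LP failed with solver status '", r$status, "'")
  }
  v <- r$x[seq_len(p$n)]
  names(v) <- model$reaction_ids
  list(pi = exp(-r$objval), J_min = r$objval, v_mp = v, status = r$status)
}

## Resolve a flux specification (reaction id/index or exchange quantity)
## into a linear functional over v.
.flux_functional <- function(model, flux) {
  n <- length(model$reaction_ids)
  if (is.character(flux)) {
    if (flux %in% model$reaction_ids) {
      f <- numeric(n); f[match(flux, model$reaction_ids)] <- 1
      return(f)
    }
    if (flux %in% model$exchange_map$quantity) {
      return(drop(exchange_functionals(model, flux)))
    }
    stop("unknown flux label: ", flux)
  }
  idx <- as.integer(flux)
  if (idx < 1L || idx > n) stop("flux index out of range: ", idx)
  f <- numeric(n); f[idx] <- 1
  f
}

#' Possibilistic interval estimate for one flux
#'
#' Bounds of the values of a flux (or measured-quantity functional) whose
#' conditional possibility — relative to the most possible state — is at
#' least `gamma`: two LPs min/max c'v subject to the model and measurement
#' constraints plus `J <= J_min - log(gamma)` (the default).  With
#' `conditional = FALSE` the bound is absolute, `J <= -log(gamma)`; the
#' interval is then empty whenever `gamma` exceeds the maximum possibility.
#'
#' @param model a `metabolic_model`.
#' @param meas a `measurement_set`.
#' @param flux reaction id, reaction index, or exchange quantity name.
#' @param gamma possibility level in (0, 1).
#' @param conditional use the conditional (relative) possibility bound.
#' @return list with `lower`, `upper`, `most_possible`, `gamma`, `empty`
#'   (TRUE when `gamma` exceeds the maximum possibility, in which case the
#'   bounds are `NA`).
#' @export
flux_interval <- function(model, meas, flux, gamma, conditional = TRUE) {
  if (!(gamma > 0 && gamma < 1)) stop("gamma must lie in (0, 1)")
  mp <- max_possibility(model, meas)
  Jcap <- if (conditional) mp$J_min - log(gamma) else -log(gamma)
  f <- .flux_functional(model, flux)
  if (!conditional && gamma > mp$pi + 1e-9) {
    return(list(lower = NA_real_, upper = NA_real_,
                most_possible = sum(f * mp$v_mp), gamma = gamma, empty = TRUE))
  }
  p <- .pmfa_lp_parts(model, meas)
  Aineq <- matrix(p$cost, 1)           # J <= Jcap
  obj <- c(f, rep(0, 4L * p$m))
  lo <- lp_solve(obj, Aeq = p$Aeq, beq = p$beq, Aineq = Aineq, bineq = Jcap,
                 lower = p$lower, upper = p$upper)
  hi <- lp_solve(obj, Aeq = p$Aeq, beq = p$beq, Aineq = Aineq, bineq = Jcap,
                 lower = p$lower, upper = p$upper, maximize = TRUE)
  if (lo$status != "optimal" && hi$status != "optimal") {
    stop("interval LPs failed: ", lo$status, " / ", hi$status)
  }
  list(lower = if (lo$status == "optimal") lo$objval else -Inf,
       upper = if (hi$status == "optimal") hi$objval else Inf,
       most_possible = sum(f * mp$v_mp), gamma = gamma, empty = FALSE)
}

#' Smallest uniform measurement band achieving full consistency
#'
#' The minimal fraction `b` such that a steady-state flux vector exists with
#' every measured quantity within `b * max(|w|, zero_floor)` of its measured
#' value — the degree of measurement uncertainty needed for complete
#' agreement between model and data (possibility 1 under a `b`-wide band).
#' Solved as a single LP.
#'
#' @param model a `metabolic_model`.
#' @param meas a `measurement_set`.
#' @return the minimal fractional band `b` (0 when the measurements are
#'   exactly feasible).
#' @export
minimal_full_band <- function(model, meas) {
  C <- attr(meas, "C")
  n <- length(model$reaction_ids); m <- nrow(meas)
  ## variables [v, b]
  Nrows <- nrow(model$N)
  Aeq <- cbind(model$N, rep(0, Nrows))
  Aineq <- rbind(cbind(C, -meas$scale),    #  Cv - b s <=  w
                 cbind(-C, -meas$scale))   # -Cv - b s <= -w
  bineq <- c(meas$w, -meas$w)
  obj <- c(rep(0, n), 1)
  r <- lp_solve(obj, Aeq = Aeq, beq = rep(0, Nrows), Aineq = Aineq,
                bineq = bineq,
                lower = c(ifelse(model$reversible, -Inf, 0), 0),
                upper = rep(Inf, n + 1L))
  if (r$status != "optimal") {
    stop("minimal-band LP failed with solver status '", r$status, "'")
  }
  max(r$objval, 0)
}

#' Possibilistic estimate of a non-measured flux
#'
#' Removes the target quantity from the measurement set (if present) and
#' returns its most possible value plus possibilistic intervals at the
#' requested levels — the leave-one-out prediction used to validate the
#' model against a measurement it was not shown.
#'
#' @param model a `metabolic_model`.
#' @param meas a `measurement_set` (the target may or may not be included;
#'   it is excluded before estimation).
#' @param target reaction id/index or exchange quantity to estimate.
#' @param gammas possibility levels for the interval estimates.
#' @param conditional passed to [flux_interval()].
#' @return list with `most_possible`, `pi` (consistency of the reduced set),
#'   and `intervals`, a data frame with one row per gamma.
#' @export
estimate_excluded_flux <- function(model, meas, target,
                                   gammas = c(0.8, 0.5, 0.1),
                                   conditional = TRUE) {
  tgt_name <- if (is.character(target)) target else model$reaction_ids[target]
  keep <- meas$quantity != tgt_name
  if (!any(keep)) stop("no measurements left after excluding the target")
  red <- meas[keep, , drop = FALSE]
  attr(red, "C") <- attr(meas, "C")[keep, , drop = FALSE]
  class(red) <- class(meas)
  mp <- max_possibility(model, red)
  f <- .flux_functional(model, target)
  iv <- lapply(gammas, function(g) {
    r <- flux_interval(model, red, target, g, conditional = conditional)
    data.frame(gamma = g, lower = r$lower, upper = r$upper, empty = r$empty)
  })
  list(most_possible = sum(f * mp$v_mp), pi = mp$pi,
       intervals = do.call(rbind, iv))
}
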