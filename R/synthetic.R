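# Synthetic inputs: random rejection batteries, feasible ground-truth flux
# vectors with noisy read-outs, and hand-verified toy networks.

#' Bounds of the two random rejection batteries
#'
#' Battery 1 draws every measured quantity uniformly in [0, 10]; battery 2
#' draws within physiologically plausible ranges (growth 1.5-6 Cmol kg⁻¹ h⁻¹,
#' substrate uptakes bounded by the observed maxima, ethanol near zero,
#' respiratory rates in the observed span).  A model that only accepts
#' genuine metabolic states should reject almost all of either battery.
#'
#' @param battery 1 or 2.
#' @return named list of `c(low, high)` bounds per measured column.
#' @export
battery_bounds <- function(battery = 1) {
  if (battery == 1) {
    b <- list(mu = c(0, 10), q_glu = c(0, 10), q_gly = c(0, 10),
              q_met = c(0, 10), q_et = c(0, 10), our = c(0, 10), cpr = c(0, 10))
  } else if (battery == 2) {
    b <- list(mu = c(1.5, 6), q_glu = c(0, 2), q_gly = c(0, 2.7),
              q_met = c(0, 2.7), q_et = c(0, 0.1), our = c(2.1, 7.2),
              cpr = c(1.5, 4))
  } else stop("battery must be 1 or 2")
  b
}

#' Generate a battery of random measurement datasets
#'
#' Each dataset draws every measured quantity independently and uniformly
#' within its bounds.
#'
#' @param bounds named list of `c(low, high)` per measured column, e.g. from
#'   [battery_bounds()].
#' @param n_datasets number of datasets.
#' @param seed RNG seed (mandatory: batteries must be reproducible).
#' @return data frame with `id` plus one column per measured quantity.
#' @export
random_battery <- function(bounds, n_datasets, seed) {
  stopifnot(n_datasets >= 1)
  bad <- vapply(bounds, function(b) length(b) != 2L || b[1] > b[2], logical(1))
  if (any(bad)) stop("invalid bounds for: ", paste(names(bounds)[bad], collapse = ", "))
  set.seed(seed)
  out <- data.frame(id = sprintf("R%04d", seq_len(n_datasets)))
  for (nm in names(bounds)) {
    out[[nm]] <- stats::runif(n_datasets, bounds[[nm]][1], bounds[[nm]][2])
  }
  out
}

#' Sample a feasible steady-state flux vector
#'
#' Draws a random nonnegative combination of elementary modes (Dirichlet
#' weights, unit concentration parameter), scaled to a target total
#' substrate uptake, so the sample satisfies the steady-state and
#' irreversibility constraints exactly.
#'
#' @param ems an `em_set` (from [enumerate_ems()]).
#' @param seed optional RNG seed.
#' @param total_uptake target summed substrate uptake in mol kg⁻¹ h⁻¹
#'   (ignored for mode sets without substrate-consuming modes).
#' @return named flux vector.
#' @export
sample_feasible_flux <- function(ems, seed = NULL, total_uptake = 1.5) {
  stopifnot(inherits(ems, "em_set"))
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(ems$modes)
  if (k == 0L) stop("empty elementary-mode set")
  wts <- stats::rgamma(k, shape = 1)
  wts <- wts / sum(wts)
  v <- drop(t(ems$modes) %*% wts)
  up <- -ems$macro[, intersect(c("glucose", "glycerol", "methanol"),
                               colnames(ems$macro)), drop = FALSE]
  tot <- sum(pmax(drop(t(up) %*% wts), 0))
  if (tot > 1e-12) v <- v * (total_uptake / tot)
  names(v) <- ems$model$reaction_ids
  v
}

#' Noisy measurement set around a known flux vector
#'
#' Reads the exchange quantities of `v` off the model, multiplies each by an
#' independent uniform factor in `[1 - rel_noise, 1 + rel_noise]`, and
#' shapes the result as a possibilistic measurement set — the ground-truth
#' generator for parameter-recovery tests.
#'
#' @param v flux vector (e.g. from [sample_feasible_flux()]).
#' @param model a `metabolic_model`.
#' @param rel_noise nonnegative relative noise amplitude.
#' @param seed optional RNG seed.
#' @param ... shaping parameters for [possibilistic_measurements()].
#' @return a `measurement_set`.
#' @export
perturb_measurements <- function(v, model, rel_noise, seed = NULL, ...) {
  stopifnot(rel_noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  C <- exchange_functionals(model)
  truth <- drop(C %*% v)
  fac <- stats::runif(length(truth), 1 - rel_noise, 1 + rel_noise)
  possibilistic_measurements(model, stats::setNames(truth * fac, rownames(C)), ...)
}

#' Library of hand-verified toy networks
#'
#' Five small networks whose elementary-mode sets are known in closed form,
#' used as oracles for the enumeration machinery:
#' \describe{
#'   \item{chain}{linear chain in → A → B → out: one mode.}
#'   \item{branch}{in → A, then A → B → out / A → C → out: two modes.}
#'   \item{rev_cycle}{an isolated fully reversible 3-cycle: one cycle mode
#'     (reported once, not with its negation) plus two through modes.}
#'   \item{diamond}{two parallel A → B routes, one reversible, closing a
#'     potential futile cycle, with uptake and efflux: two through modes
#'     plus the internal cycle.}
#'   \item{choice}{two substrates feeding a common intermediate with one
#'     efflux: one mode per substrate.}
#' }
#'
#' @return named list; each element has `model` and `n_ems` (the
#'   hand-derived mode count).
#' @export
toy_networks <- function() {
  out <- list()

  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("v1", "v2", "v3")))
  out$chain <- list(model = metabolic_model(S, reversible = c(FALSE, FALSE, FALSE)),
                    n_ems = 1L)

  S <- matrix(c(1, -1, 0, -1, 0,
                0, 1, -1, 0, 0,
                0, 0, 0, 1, -1), 3, 5, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("v", 1:5)))
  out$branch <- list(model = metabolic_model(S, reversible = rep(FALSE, 5)),
                     n_ems = 2L)

  ## A <-> B <-> C <-> A reversible cycle with irreversible in/out at A and C
  S <- matrix(c(-1, 0, 1, 1, 0,
                1, -1, 0, 0, 0,
                0, 1, -1, 0, -1), 3, 5, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c("ab", "bc", "ca", "in_a", "out_c")))
  out$rev_cycle <- list(model = metabolic_model(S, reversible = c(TRUE, TRUE, TRUE,
                                                                  FALSE, FALSE)),
                        n_ems = 3L)

  ## diamond with a futile pair: u: ->A; p: A->B (irr); q: A<->B (rev); e: B->
  S <- matrix(c(1, -1, -1, 0,
                0, 1, 1, -1), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), c("u", "p", "q", "e")))
  out$diamond <- list(model = metabolic_model(S, reversible = c(FALSE, FALSE, TRUE,
                                                                FALSE)),
                      n_ems = 3L)

  ## substrate choice: s1: ->A; s2: ->A; e: A->
  S <- matrix(c(1, 1, -1), 1, 3,
              dimnames = list("A", c("s1", "s2", "e")))
  out$choice <- list(model = metabolic_model(S, reversible = rep(FALSE, 3)),
                     n_ems = 2L)
  out
}
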