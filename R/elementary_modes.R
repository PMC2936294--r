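# Elementary flux mode enumeration and analysis.
#
# Reversible reactions are split into forward/backward pairs so the flux
# cone becomes pointed ({x >= 0, A x = 0}); its extreme rays are computed by
# an incremental double-description algorithm with the combinatorial
# adjacency test, then the split pairs are re-fused, futile two-cycle
# artefacts removed, and sign duplicates of fully reversible modes
# collapsed.  This is exact for networks of the size targeted here
# (tens of reactions, hundreds of modes).

#' Enumerate the elementary flux modes of a model
#'
#' @param model a `metabolic_model`.
#' @param tol zero tolerance applied after canonical scaling.
#' @param max_modes resource cap: enumeration stops with an error (never a
#'   silent truncation) if the working set of candidate rays exceeds it.
#' @return an object of class `em_set`: list with `modes` (matrix, one row
#'   per elementary mode, reactions as columns, canonical scaling),
#'   `macro` (matrix of net production per exchanged quantity; substrate
#'   consumption is negative), `category` (data frame of per-mode flags:
#'   uses_glucose/uses_glycerol/uses_methanol/produces_biomass/
#'   produces_ethanol) and `model`.
#'
#' Canonical scaling: each mode is scaled so the summed molar uptake of the
#' consumed carbon substrates equals 1; modes consuming no substrate are
#' scaled to a largest absolute coefficient of 1.
#' @export
#' @examples
#' toy <- toy_networks()$chain$model
#' enumerate_ems(toy)$modes
enumerate_ems <- function(model, tol = 1e-9, max_modes = 200000L) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- length(model$reaction_ids)
  if (n < 1L) stop("model has no reactions")
  rev_idx <- which(model$reversible)
  A <- model$N
  if (length(rev_idx)) A <- cbind(A, -model$N[, rev_idx, drop = FALSE])
  nx <- ncol(A)

  R <- extreme_rays_pointed(A, max_rays = max_modes, tol = tol)

  ## re-fuse split columns: v = x_fwd - x_bwd
  V <- R[, seq_len(n), drop = FALSE]
  if (length(rev_idx)) {
    V[, rev_idx] <- V[, rev_idx, drop = FALSE] - R[, n + seq_along(rev_idx), drop = FALSE]
  }
  ## drop futile two-cycles (v == 0) and scale
  keep <- apply(abs(V), 1, max) > tol
  V <- V[keep, , drop = FALSE]
  V <- V / apply(abs(V), 1, max)
  V[abs(V) < tol] <- 0

  ## canonical sign: modes with no active irreversible reaction appear as
  ## +/- pairs; orient so the first nonzero entry is positive.
  irr <- !model$reversible
  for (i in seq_len(nrow(V))) {
    if (!any(V[i, irr] > tol)) {
      j <- which(abs(V[i, ]) > tol)[1]
      if (V[i, j] < 0) V[i, ] <- -V[i, ]
    }
  }
  ## deduplicate up to positive scaling
  key <- apply(V, 1, function(v) {
    v <- v / max(abs(v))
    paste(round(v, 9), collapse = ",")
  })
  V <- V[!duplicated(key), , drop = FALSE]

  ## canonical scaling by substrate uptake
  macro_all <- exchange_functionals(model)
  subs <- intersect(c("glucose", "glycerol", "methanol"), rownames(macro_all))
  up <- if (length(subs)) macro_all[subs, , drop = FALSE] %*% t(V) else
    matrix(0, 0, nrow(V))                          # uptake rates per mode
  for (i in seq_len(nrow(V))) {
    tot <- sum(pmax(up[, i], 0))
    if (tot > tol) V[i, ] <- V[i, ] / tot else V[i, ] <- V[i, ] / max(abs(V[i, ]))
  }
  V[abs(V) < tol] <- 0
  colnames(V) <- model$reaction_ids
  rownames(V) <- sprintf("em%03d", seq_len(nrow(V)))

  macro <- V %*% t(macro_all)   # modes x quantities, uptake positive for uptakes
  ## convert to net production convention: substrates negative when consumed
  if (ncol(macro)) {
    prod_sign <- ifelse(model$exchange_map$direction[match(colnames(macro),
                          model$exchange_map$quantity)] == "uptake", -1, 1)
    macro <- sweep(macro, 2, prod_sign, `*`)
  }
  qcol <- function(q) if (q %in% colnames(macro)) macro[, q] else rep(0, nrow(V))
  category <- data.frame(
    uses_glucose  = qcol("glucose")  < -tol,
    uses_glycerol = qcol("glycerol") < -tol,
    uses_methanol = qcol("methanol") < -tol,
    produces_biomass = qcol("biomass") > tol,
    produces_ethanol = qcol("ethanol") > tol,
    row.names = rownames(V)
  )
  structure(list(modes = V, macro = macro, category = category, model = model),
            class = "em_set")
}

## Incremental double description for {x >= 0, A x = 0}; returns rays as rows.
extreme_rays_pointed <- function(A, max_rays = 200000L, tol = 1e-9) {
  m <- nrow(A); nx <- ncol(A)
  R <- diag(nx)                      # rays as rows
  if (m == 0L) return(R)
  ## order rows by increasing number of nonzeros (keeps intermediate sets small)
  ord <- order(rowSums(A != 0))
  for (i in ord) {
    s <- drop(R %*% A[i, ])
    sc <- max(abs(s), 1)
    pos <- which(s > tol * sc); neg <- which(s < -tol * sc)
    zer <- setdiff(seq_len(nrow(R)), c(pos, neg))
    if (!length(pos) || !length(neg)) {
      R <- R[zer, , drop = FALSE]
      if (nrow(R) == 0L) return(R)
      next
    }
    supp <- R > tol                   # support pattern of current rays
    new_list <- list()
    for (p in pos) {
      ## combine with all negative rays; adjacency via support-subset test
      up <- supp[p, ]
      cand <- neg
      if (length(cand)) {
        U <- !(matrix(up, length(cand), nx, byrow = TRUE) | supp[cand, , drop = FALSE])
        ## counts of support outside the union, for every existing ray
        M <- supp %*% t(U)            # nrays x ncand
        for (ci in seq_along(cand)) {
          q <- cand[ci]
          inside <- which(M[, ci] == 0L)
          if (length(setdiff(inside, c(p, q))) == 0L) {
            r_new <- s[p] * R[q, ] - s[q] * R[p, ]
            r_new[r_new < 0 & r_new > -1e-12 * max(abs(r_new))] <- 0
            new_list[[length(new_list) + 1L]] <- r_new / max(abs(r_new))
          }
        }
      }
    }
    R <- rbind(R[zer, , drop = FALSE],
               if (length(new_list)) do.call(rbind, new_list))
    if (nrow(R) > max_rays) {
      stop("elementary-mode enumeration exceeded the configured cap of ",
           max_rays, " rays; raise 'max_modes' explicitly")
    }
  }
  R
}

#' Classify an elementary-mode set and count categories
#'
#' @param ems an `em_set`.
#' @return list with `counts`: named counts (total, non_growth,
#'   ethanol_producing, and per substrate-combination growth-mode counts)
#'   and the per-mode `category` table.
#' @export
classify_ems <- function(ems) {
  stopifnot(inherits(ems, "em_set"))
  cat <- ems$category
  combo <- substrate_combo(cat)
  growth <- cat$produces_biomass
  counts <- c(total = nrow(cat),
              non_growth = sum(!growth),
              ethanol_producing = sum(cat$produces_ethanol))
  tab <- table(combo[growth])
  list(counts = counts, growth_by_substrate = tab, category = cat,
       substrate_combo = combo)
}

substrate_combo <- function(cat) {
  lab <- character(nrow(cat))
  for (i in seq_len(nrow(cat))) {
    u <- c("glucose", "glycerol", "methanol")[c(cat$uses_glucose[i],
                                                cat$uses_glycerol[i],
                                                cat$uses_methanol[i])]
    lab[i] <- if (length(u)) paste(u, collapse = "+") else "none"
  }
  lab
}

#' Biomass carbon yield of one elementary mode
#'
#' @param ems an `em_set`.
#' @param mode mode index or row name.
#' @param basis `"per_mol"`: Cmol biomass per total mol of consumed carbon
#'   substrates; `"per_cmol"`: Cmol biomass per Cmol of substrate carbon.
#' @return numeric yield (0 for non-growth modes).
#' @export
em_yield <- function(ems, mode, basis = c("per_mol", "per_cmol")) {
  basis <- match.arg(basis)
  stopifnot(inherits(ems, "em_set"))
  mac <- ems$macro[mode, ]
  subs <- c("glucose", "glycerol", "methanol")
  upt <- vapply(subs, function(q) {
    if (q %in% names(mac)) max(-mac[[q]], 0) else 0
  }, numeric(1))
  if (sum(upt) <= 0) stop("mode consumes no carbon substrate: yield undefined")
  biomass <- if ("biomass" %in% names(mac)) max(mac[["biomass"]], 0) else 0
  if (basis == "per_mol") return(unname(biomass / sum(upt)))
  cc <- c(glucose = 6, glycerol = 3, methanol = 1)
  unname(biomass / sum(upt * cc))
}

#' Maximum theoretical yields per substrate combination
#'
#' For each combination of carbon substrates consumed by at least one
#' biomass-producing mode, the maximum per-mol yield (Cmol DW per mol of
#' summed substrate uptake) over the growth modes consuming exactly that
#' combination, with the index of the attaining mode (ties broken by the
#' lowest mode id).
#'
#' @param ems an `em_set`.
#' @return data frame with columns `substrates`, `max_yield`, `mode`.
#' @export
max_yield_per_category <- function(ems) {
  stopifnot(inherits(ems, "em_set"))
  cl <- classify_ems(ems)
  growth <- which(ems$category$produces_biomass)
  combos <- cl$substrate_combo[growth]
  ylds <- vapply(growth, function(i) em_yield(ems, i, "per_mol"), numeric(1))
  out <- do.call(rbind, lapply(split(seq_along(growth), combos), function(ii) {
    best <- ii[which.max(ylds[ii])]
    data.frame(substrates = combos[ii[1]], max_yield = ylds[best],
               mode = rownames(ems$modes)[growth[best]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[out$substrates != "none", , drop = FALSE]
}

#' @export
print.em_set <- function(x, ...) {
  cl <- classify_ems(x)
  cat("em_set:", nrow(x$modes), "elementary modes;",
      cl$counts["non_growth"], "without biomass formation;",
      cl$counts["ethanol_producing"], "producing ethanol\n")
  invisible(x)
}
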