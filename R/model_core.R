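# Constraint-based model container and reaction-table I/O.
#
# A model is the pair (N, D) of the steady-state constraint set
#     N v = 0,   D v >= 0
# over n reaction fluxes v, where N holds the rows of the stoichiometric
# matrix for the balanced (internal) metabolites and D marks irreversible
# reactions.  The full stoichiometry S (external rows included) is kept so
# that exchange rates of external species can be read off any flux vector.

#' Read a metabolic model from a reaction-table file
#'
#' The plain-text format has three tab-separated sections introduced by
#' `[metabolites]`, `[reactions]` and `[exchanges]` headers.  Metabolites
#' carry an internal/external flag and a carbon count; reactions are written
#' as equation strings (`"2 A + B -> C"`, with `"<->"` marking reversible
#' reactions); the exchange section maps measurable quantities (glucose,
#' biomass, ...) onto external species and a sign convention (`uptake`
#' rates are positive when the species is consumed, `production` rates when
#' it is formed).
#'
#' @param path path to the model file.
#' @return an object of class `metabolic_model` with components
#'   `reaction_ids`, `metabolite_ids`, `internal` (logical), `carbons`
#'   (named numeric, carbon atoms per mole), `S` (full stoichiometric
#'   matrix, metabolites x reactions), `N` (internal rows of `S`),
#'   `reversible` (logical per reaction), `reaction_names`, and
#'   `exchange_map` (data frame with columns `quantity`, `metabolite`,
#'   `direction`).
#' @export
#' @examples
#' mod <- pichia_model()
#' dim(mod$N)
read_metabolic_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- tolower(gsub("[][]", "", lines[grepl("^\\[", lines)]))
  blocks <- split(lines[!grepl("^\\[", lines)], sec[!grepl("^\\[", lines)])
  names(blocks) <- headers[as.integer(names(blocks))]
  need <- c("metabolites", "reactions")
  if (!all(need %in% names(blocks))) {
    stop("model file must contain [metabolites] and [reactions] sections")
  }
  parse_block <- function(x) {
    con <- textConnection(paste(x, collapse = "\n"))
    on.exit(close(con))
    utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  }
  mets <- parse_block(blocks[["metabolites"]])
  rxns <- parse_block(blocks[["reactions"]])
  exch <- if ("exchanges" %in% names(blocks)) parse_block(blocks[["exchanges"]]) else
    data.frame(quantity = character(0), metabolite = character(0),
               direction = character(0), stringsAsFactors = FALSE)

  if (nrow(rxns) == 0L) stop("model format error: empty model (no reactions)")
  if (anyDuplicated(rxns$id)) {
    stop("model format error: duplicate reaction id: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  if (anyDuplicated(mets$id)) {
    stop("model format error: duplicate metabolite id: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }

  met_ids <- mets$id
  n <- nrow(rxns)
  S <- matrix(0, nrow(mets), n, dimnames = list(met_ids, rxns$id))
  reversible <- logical(n)
  for (j in seq_len(n)) {
    eq <- parse_reaction_equation(rxns$equation[j])
    reversible[j] <- eq$reversible
    unknown <- setdiff(names(eq$coef), met_ids)
    if (length(unknown)) {
      stop("model format error: undeclared metabolite(s) in reaction ",
           rxns$id[j], ": ", paste(unknown, collapse = ", "))
    }
    S[names(eq$coef), j] <- S[names(eq$coef), j] + eq$coef
  }
  if (any(colSums(S != 0) == 0L)) {
    stop("model format error: reaction touching no metabolite")
  }
  internal <- as.logical(mets$internal)
  names(internal) <- met_ids
  carbons <- as.numeric(mets$carbons)
  names(carbons) <- met_ids
  if (nrow(exch)) {
    bad <- setdiff(exch$metabolite, met_ids)
    if (length(bad)) stop("model format error: exchange entry for undeclared metabolite: ",
                          paste(bad, collapse = ", "))
    if (any(internal[exch$metabolite])) {
      stop("model format error: exchange quantities must map to external species")
    }
    if (!all(exch$direction %in% c("uptake", "production"))) {
      stop("model format error: exchange direction must be 'uptake' or 'production'")
    }
  }
  structure(list(
    reaction_ids = rxns$id,
    metabolite_ids = met_ids,
    internal = internal,
    carbons = carbons,
    S = S,
    N = S[internal, , drop = FALSE],
    reversible = reversible,
    reaction_names = if ("name" %in% names(rxns)) rxns$name else rep("", n),
    metabolite_names = if ("name" %in% names(mets)) mets$name else rep("", nrow(mets)),
    exchange_map = exch
  ), class = "metabolic_model")
}

#' Construct a metabolic model from matrices
#'
#' Programmatic constructor used for toy networks and tests; the file reader
#' [read_metabolic_model()] is the usual entry point for real models.
#'
#' @param S full stoichiometric matrix (metabolites x reactions); row and
#'   column names are used as identifiers (defaults generated if absent).
#' @param reversible logical per reaction.
#' @param internal logical per metabolite (default: all internal).
#' @param carbons carbon atoms per mole of each metabolite (default 1).
#' @param exchange_map optional data frame with columns `quantity`,
#'   `metabolite`, `direction`.
#' @return a `metabolic_model`.
#' @export
metabolic_model <- function(S, reversible, internal = rep(TRUE, nrow(S)),
                            carbons = rep(1, nrow(S)), exchange_map = NULL) {
  S <- as.matrix(S)
  if (is.null(rownames(S))) rownames(S) <- paste0("M", seq_len(nrow(S)))
  if (is.null(colnames(S))) colnames(S) <- paste0("v", seq_len(ncol(S)))
  stopifnot(length(reversible) == ncol(S), length(internal) == nrow(S))
  if (any(colSums(S != 0) == 0L)) stop("reaction touching no metabolite")
  if (is.null(exchange_map)) {
    exchange_map <- data.frame(quantity = character(0), metabolite = character(0),
                               direction = character(0), stringsAsFactors = FALSE)
  }
  internal <- stats::setNames(as.logical(internal), rownames(S))
  structure(list(
    reaction_ids = colnames(S), metabolite_ids = rownames(S),
    internal = internal,
    carbons = stats::setNames(as.numeric(carbons), rownames(S)),
    S = S, N = S[internal, , drop = FALSE],
    reversible = as.logical(reversible),
    reaction_names = rep("", ncol(S)), metabolite_names = rep("", nrow(S)),
    exchange_map = exchange_map
  ), class = "metabolic_model")
}

#' The shipped Pichia pastoris central-carbon model
#'
#' A 44-reaction, 45-compound stoichiometric model of the central carbon
#' metabolism of *Pichia pastoris* growing on glucose, glycerol and/or
#' methanol: EMP glycolysis, TCA cycle with glyoxylate shunt, pentose
#' phosphate pathway, fermentative branch, methanol oxidation and
#' assimilation, glycerol uptake, with separate cytosolic and mitochondrial
#' pools for pyruvate, acetyl-CoA, oxaloacetate and reduced cofactors, and a
#' lumped biomass equation scaled to 1 Cmol dry weight.  36 internal
#' metabolites are balanced; the model has 8 degrees of freedom.  Energy
#' cofactors (ATP) are not balanced.
#'
#' @return a `metabolic_model` object.
#' @export
pichia_model <- function() {
  read_metabolic_model(system.file("extdata", "pichia_ccm.tsv",
                                   package = "possMFA", mustWork = TRUE))
}

#' Write a metabolic model back to the reaction-table format
#'
#' Inverse of [read_metabolic_model()]: the written file parses back into a
#' model with identical stoichiometry, reversibility and exchange map.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  fmt_num <- function(x) {
    s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
    sub("\\.?0+$", "", s)
  }
  eqs <- vapply(seq_along(model$reaction_ids), function(j) {
    col <- model$S[, j]
    lhs <- which(col < 0); rhs <- which(col > 0)
    side <- function(idx, sgn) {
      if (!length(idx)) return("")
      paste(vapply(idx, function(i) {
        cf <- abs(col[i])
        if (abs(cf - 1) < 1e-12) model$metabolite_ids[i]
        else paste(fmt_num(cf), model$metabolite_ids[i])
      }, character(1)), collapse = " + ")
    }
    arrow <- if (model$reversible[j]) "<->" else "->"
    paste(side(lhs), arrow, side(rhs))
  }, character(1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# possMFA reaction-table model", con)
  writeLines("[metabolites]", con)
  writeLines("id\tinternal\tcarbons\tname", con)
  writeLines(paste(model$metabolite_ids, as.integer(model$internal),
                   fmt_num(model$carbons), model$metabolite_names, sep = "\t"), con)
  writeLines("[reactions]", con)
  writeLines("id\tequation\tname", con)
  writeLines(paste(model$reaction_ids, eqs, model$reaction_names, sep = "\t"), con)
  if (nrow(model$exchange_map)) {
    writeLines("[exchanges]", con)
    writeLines("quantity\tmetabolite\tdirection", con)
    writeLines(paste(model$exchange_map$quantity, model$exchange_map$metabolite,
                     model$exchange_map$direction, sep = "\t"), con)
  }
  invisible(path)
}

## Parse "2 A + 0.5 B -> C" / "A <-> B" into coefficient vector + flag.
parse_reaction_equation <- function(eq) {
  reversible <- grepl("<->", eq, fixed = TRUE)
  parts <- if (reversible) strsplit(eq, "<->", fixed = TRUE)[[1]] else
    strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("cannot parse reaction equation: ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      toks <- strsplit(tm, "\\s+")[[1]]
      if (length(toks) == 1L) { cf <- 1; id <- toks }
      else if (length(toks) == 2L) {
        cf <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(cf)) stop("bad coefficient in term '", tm, "' of: ", eq)
        id <- toks[2]
      } else stop("cannot parse term '", tm, "' of: ", eq)
      out[id] <- (if (id %in% names(out)) out[id] else 0) + sign * cf
    }
    out
  }
  lhs <- parse_side(parts[1], -1)
  rhs <- parse_side(parts[2], +1)
  coef <- lhs
  for (id in names(rhs)) coef[id] <- (if (id %in% names(coef)) coef[id] else 0) + rhs[id]
  coef <- coef[coef != 0]
  list(coef = coef, reversible = reversible)
}

#' Numerical rank of a matrix by singular values
#'
#' Rank with tolerance `max(dim(A)) * eps * max(singular value)`.
#' @param A numeric matrix.
#' @keywords internal
#' @noRd
mat_rank <- function(A) {
  if (nrow(A) == 0L || ncol(A) == 0L) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * max(sv, 0)
  sum(sv > tol)
}

#' Degrees of freedom of a constraint-based model
#'
#' Number of reactions minus the rank of the internal stoichiometric matrix:
#' the dimension of the steady-state flux space before irreversibility is
#' imposed.
#'
#' @param model a `metabolic_model`.
#' @return integer.
#' @export
#' @examples
#' degrees_of_freedom(pichia_model())  # 8
degrees_of_freedom <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  length(model$reaction_ids) - mat_rank(model$N)
}

#' Linear functionals mapping fluxes to measured exchange rates
#'
#' For each requested quantity, the corresponding row of the returned matrix
#' applied to a flux vector gives the exchange rate of the mapped external
#' species with the model's sign convention (uptakes positive for consumed
#' substrates, production rates positive for formed products).
#'
#' @param model a `metabolic_model`.
#' @param quantities character; default all quantities in the exchange map.
#' @return matrix (quantities x reactions) with quantity row names.
#' @export
exchange_functionals <- function(model, quantities = model$exchange_map$quantity) {
  em <- model$exchange_map
  missing_q <- setdiff(quantities, em$quantity)
  if (length(missing_q)) {
    stop("no exchange mapping for quantity: ", paste(missing_q, collapse = ", "))
  }
  C <- matrix(0, length(quantities), length(model$reaction_ids),
              dimnames = list(quantities, model$reaction_ids))
  for (q in quantities) {
    row <- em[em$quantity == q, ][1, ]
    sgn <- if (row$direction == "uptake") -1 else 1
    C[q, ] <- sgn * model$S[row$metabolite, ]
  }
  C
}

#' Independent constraints added by a set of measurements
#'
#' Rank of the internal stoichiometric matrix stacked with the measurement
#' functionals, minus the rank of the stoichiometric matrix alone: the
#' number of genuinely independent linear constraints that the measurements
#' contribute to flux estimation.
#'
#' @param model a `metabolic_model`.
#' @param measured either a character vector of exchange-map quantities, a
#'   numeric vector of reaction indices (selector rows), or a matrix of
#'   measurement functionals (rows, `n` columns).
#' @return integer.
#' @export
measurement_rank <- function(model, measured) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- length(model$reaction_ids)
  C <- if (is.matrix(measured)) {
    stopifnot(ncol(measured) == n)
    measured
  } else if (is.character(measured)) {
    exchange_functionals(model, measured)
  } else {
    idx <- as.integer(measured)
    if (any(idx < 1L | idx > n)) stop("invalid reaction index in 'measured'")
    M <- matrix(0, length(idx), n)
    M[cbind(seq_along(idx), idx)] <- 1
    M
  }
  mat_rank(rbind(model$N, C)) - mat_rank(model$N)
}

#' Check a flux vector for steady state and irreversibility
#'
#' @param model a `metabolic_model`.
#' @param v numeric flux vector of length `n`.
#' @param tol nonnegative tolerance on the balance residual and on
#'   irreversibility violations.
#' @return list with `ok` (logical), `max_residual` (largest absolute entry
#'   of `N v`) and `irrev_violation` (largest negative irreversible flux, as
#'   a nonnegative magnitude).
#' @export
check_steady_state <- function(model, v, tol = 1e-8) {
  stopifnot(inherits(model, "metabolic_model"), tol > 0)
  if (length(v) != length(model$reaction_ids)) {
    stop("flux vector length ", length(v), " does not match model size ",
         length(model$reaction_ids))
  }
  if (!all(is.finite(v))) stop("flux vector must be finite")
  resid <- if (nrow(model$N)) max(abs(model$N %*% v)) else 0
  irr <- !model$reversible
  viol <- if (any(irr)) max(c(0, -v[irr])) else 0
  list(ok = resid <= tol && viol <= tol, max_residual = resid,
       irrev_violation = viol)
}

#' Audit elemental (carbon) consistency of every reaction
#'
#' Computes, per reaction, the net carbon created (positive) or destroyed
#' (negative) given the declared carbon counts.  For a well-formed model all
#' entries are zero: carbon then balances automatically across any
#' steady-state flux distribution.
#'
#' @param model a `metabolic_model`.
#' @return named numeric vector of per-reaction carbon imbalances.
#' @export
carbon_balance_audit <- function(model) {
  drop(model$carbons %*% model$S)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$reaction_ids), "reactions,",
      length(x$metabolite_ids), "compounds (",
      sum(x$internal), "internal ),",
      sum(x$reversible), "reversible\n")
  cat("degrees of freedom:", degrees_of_freedom(x), "\n")
  if (nrow(x$exchange_map)) {
    cat("exchange quantities:", paste(x$exchange_map$quantity, collapse = ", "), "\n")
  }
  invisible(x)
}
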