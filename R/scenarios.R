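# The eleven published culture datasets and their mapping onto the model.

#' Load the shipped experimental datasets
#'
#' Eleven chemostat/fed-batch datasets for *P. pastoris* cultures growing on
#' glucose (D1), glycerol (A1, B1) and glycerol/methanol mixtures, compiled
#' from three independent literature groups.  Rates: biomass `mu` in
#' Cmol kg⁻¹ h⁻¹, substrate/gas rates in mol kg⁻¹ h⁻¹, protein productivity
#' `q_p` in mg g⁻¹ h⁻¹.
#'
#' @return data frame with columns `id`, `ref_group`, `mu`, `q_glu`,
#'   `q_gly`, `q_met`, `q_et`, `our`, `cpr`, `q_p`.
#' @export
load_scenarios <- function() {
  path <- system.file("extdata", "chemostat_datasets.tsv", package = "possMFA",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

## Table-2 column -> exchange quantity names in the model.
.scenario_quantities <- c(mu = "biomass", q_glu = "glucose", q_gly = "glycerol",
                          q_met = "methanol", q_et = "ethanol",
                          our = "o2", cpr = "co2")

#' Scenario row as a named measurement vector
#'
#' @param s one-row data frame (a row of [load_scenarios()]).
#' @return named numeric vector keyed by exchange quantity.
#' @export
scenario_values <- function(s) {
  stopifnot(nrow(s) == 1L)
  v <- as.numeric(s[, names(.scenario_quantities)])
  stats::setNames(v, unname(.scenario_quantities))
}

#' Convert a scenario into a possibilistic measurement set
#'
#' Maps each measured column (biomass, substrates, ethanol, gas rates) onto
#' the model's exchange quantities and shapes the possibility distributions
#' with [shape_measurement()] defaults.  Zero-valued rates are kept as
#' measurements (with the `zero_floor` scale) rather than dropped: a zero
#' ethanol rate genuinely constrains the fermentative branch.  The protein
#' productivity `q_p` is excluded unless `include_qp` and the model carries
#' a protein efflux quantity; the shipped model does not represent the
#' resources devoted to recombinant protein and therefore has none.
#'
#' @param s one-row scenario data frame.
#' @param model a `metabolic_model`.
#' @param include_qp map `q_p` onto a `protein` exchange quantity.
#' @param ... shaping parameters passed to [possibilistic_measurements()].
#' @return a `measurement_set`.
#' @export
to_measurements <- function(s, model, include_qp = FALSE, ...) {
  vals <- scenario_values(s)
  missing_q <- setdiff(names(vals), model$exchange_map$quantity)
  if (length(missing_q)) {
    stop("model exchange map lacks quantities: ", paste(missing_q, collapse = ", "))
  }
  if (include_qp) {
    if (!"protein" %in% model$exchange_map$quantity) {
      stop("include_qp = TRUE but the model has no 'protein' exchange quantity")
    }
    vals <- c(vals, protein = as.numeric(s$q_p))
  }
  possibilistic_measurements(model, vals, ...)
}

#' Experimental biomass yield of a scenario
#'
#' Biomass formation per mole of summed carbon-substrate uptake,
#' `mu / (q_glu + q_gly + q_met)`, in Cmol DW per mol.
#'
#' @param s one-row scenario data frame.
#' @return numeric yield.
#' @export
experimental_yield <- function(s) {
  tot <- s$q_glu + s$q_gly + s$q_met
  if (tot <= 0) stop("scenario has no substrate uptake: yield undefined")
  s$mu / tot
}

#' Compare a scenario's experimental yield with the theoretical maximum
#'
#' Pairs the experimental yield with the maximal elementary-mode yield of
#' the substrate combination the scenario uses.
#'
#' @param s one-row scenario data frame.
#' @param ems an `em_set` of the model.
#' @return data frame with `id`, `substrates`, `exp_yield`, `max_theoretical`,
#'   `violated`.
#' @export
yield_vs_theoretical <- function(s, ems) {
  combo <- paste(c("glucose", "glycerol", "methanol")[c(s$q_glu > 0, s$q_gly > 0,
                                                        s$q_met > 0)],
                 collapse = "+")
  tab <- max_yield_per_category(ems)
  theo <- tab$max_yield[tab$substrates == combo]
  if (!length(theo)) theo <- NA_real_
  ey <- experimental_yield(s)
  data.frame(id = s$id, substrates = combo, exp_yield = ey,
             max_theoretical = theo,
             violated = !is.na(theo) & ey > theo,
             stringsAsFactors = FALSE)
}
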