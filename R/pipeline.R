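# End-to-end validation pipeline: yields vs theory, consistency columns,
# leave-growth-out prediction, per-flux sign patterns, rejection batteries.

#' Default pipeline configuration
#'
#' @return named list: possibility shaping (`full_band` 0.05, `ref_band`
#'   0.20, `ref_possibility` 0.1, `zero_floor` 0.05 mol kg⁻¹ h⁻¹), WLS
#'   `rel_sd` 0.10, interval levels `gammas` (0.8, 0.5, 0.1), battery sizes
#'   and seed.
#' @export
default_config <- function() {
  list(full_band = 0.05, ref_band = 0.20, ref_possibility = 0.1,
       zero_floor = 0.05, rel_sd = 0.10, gammas = c(0.8, 0.5, 0.1),
       battery_n = 500L, seed = 20101L)
}

#' Run the full model-validation study
#'
#' For every scenario: the experimental yield against the theoretical
#' maximum of its substrate combination, the weighted least-squares residual
#' `phi`, the maximum possibility `pi`, the minimal uniform band to full
#' consistency (half-width `band_to_full`, and `band_full_width = 2x` as
#' printed in consistency tables), and the leave-growth-out prediction of
#' `mu` with possibilistic intervals.  Optionally evaluates the random
#' rejection batteries.
#'
#' @param model a `metabolic_model`.
#' @param scenarios scenario data frame ([load_scenarios()] layout).
#' @param config list from [default_config()] (entries may be overridden).
#' @param ems optional precomputed `em_set` (enumerated if `NULL`).
#' @param batteries logical: run the two random rejection batteries.
#' @return object of class `validation_report`: list with `scenario_table`,
#'   `growth_prediction` (one row per scenario x gamma), `em_summary`,
#'   `yield_table`, `battery` (or `NULL`), and the `config` used.
#' @export
run_validation <- function(model, scenarios, config = default_config(),
                           ems = NULL, batteries = FALSE) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(ems)) ems <- enumerate_ems(model)
  cl <- classify_ems(ems)

  yield_rows <- list(); srows <- list(); pred_rows <- list()
  for (i in seq_len(nrow(scenarios))) {
    s <- scenarios[i, , drop = FALSE]
    meas <- to_measurements(s, model, full_band = cfg$full_band,
                            ref_band = cfg$ref_band,
                            ref_possibility = cfg$ref_possibility,
                            zero_floor = cfg$zero_floor)
    mp <- max_possibility(model, meas)
    b <- minimal_full_band(model, meas)
    w <- wls_residual(model, scenario_values(s), rel_sd = cfg$rel_sd,
                      zero_floor = cfg$zero_floor)
    yd <- yield_vs_theoretical(s, ems)
    pred <- estimate_excluded_flux(model, meas, "biomass", gammas = cfg$gammas)
    srows[[i]] <- data.frame(id = s$id, phi = w$phi, pi = mp$pi,
                             band_to_full = b, band_full_width = 2 * b,
                             mu_most_possible = pred$most_possible,
                             stringsAsFactors = FALSE)
    yield_rows[[i]] <- yd
    pr <- pred$intervals
    pr$id <- s$id; pr$mu_measured <- s$mu; pr$mu_hat <- pred$most_possible
    pr$covered <- !pr$empty & pr$lower <= s$mu & s$mu <= pr$upper
    pred_rows[[i]] <- pr
  }
  empty_df <- function(cols) {
    as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  }
  report <- list(
    scenario_table = if (length(srows)) do.call(rbind, srows) else
      empty_df(c("id", "phi", "pi", "band_to_full", "band_full_width",
                 "mu_most_possible")),
    yield_table = if (length(yield_rows)) do.call(rbind, yield_rows) else
      empty_df(c("id", "substrates", "exp_yield", "max_theoretical", "violated")),
    growth_prediction = if (length(pred_rows)) do.call(rbind, pred_rows) else
      empty_df(c("gamma", "lower", "upper", "empty", "id", "mu_measured",
                 "mu_hat", "covered")),
    em_summary = list(counts = cl$counts,
                      max_yields = max_yield_per_category(ems)),
    battery = NULL,
    config = cfg
  )
  if (batteries) {
    report$battery <- lapply(1:2, function(bi) {
      battery_rejection(model, battery = bi, n = cfg$battery_n,
                        seed = cfg$seed + bi, config = cfg)
    })
  }
  class(report) <- "validation_report"
  report
}

#' Rejection rate of a random measurement battery
#'
#' Draws `n` random datasets within the battery bounds and reports the
#' fraction whose maximum possibility falls below `pi_threshold` — the
#' model's ability to reject flux patterns that are not genuine metabolic
#' states.
#'
#' @param model a `metabolic_model`.
#' @param battery 1 (uninformative, every rate in 0-10) or 2
#'   (physiologically plausible ranges); see [battery_bounds()].
#' @param n number of random datasets.
#' @param seed RNG seed.
#' @param pi_threshold rejection threshold on the possibility.
#' @param config shaping configuration ([default_config()]).
#' @return list with `fraction_rejected`, `pi` (vector), `n`, `battery`.
#' @export
battery_rejection <- function(model, battery, n, seed, pi_threshold = 0.1,
                              config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  rb <- random_battery(battery_bounds(battery), n, seed)
  pis <- vapply(seq_len(nrow(rb)), function(i) {
    meas <- to_measurements(rb[i, ], model, full_band = cfg$full_band,
                            ref_band = cfg$ref_band,
                            ref_possibility = cfg$ref_possibility,
                            zero_floor = cfg$zero_floor)
    max_possibility(model, meas)$pi
  }, numeric(1))
  list(fraction_rejected = mean(pis < pi_threshold), pi = pis, n = n,
       battery = battery)
}

#' Sign pattern of key branchpoint fluxes across scenarios
#'
#' Most-possible values and signs (at a tolerance) of selected fluxes for
#' every scenario: by default the upper-glycolysis block (v02-v04, which
#' reverses to gluconeogenesis on glycerol/methanol), the pentose-phosphate
#' isomerisation block (v21-v23) and the methanol branchpoint (v32-v34).
#'
#' @param model a `metabolic_model`.
#' @param scenarios scenario data frame.
#' @param fluxes character vector of reaction ids.
#' @param tol absolute tolerance below which a flux is reported as 0.
#' @param config shaping configuration.
#' @return data frame: one row per scenario, one column per flux holding the
#'   most-possible value, plus matching `sign_*` columns with `"+"`, `"-"`,
#'   `"0"`.
#' @export
flux_sign_report <- function(model, scenarios,
                             fluxes = c("v02", "v03", "v04", "v21", "v22",
                                        "v23", "v32", "v33", "v34"),
                             tol = 1e-6, config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  bad <- setdiff(fluxes, model$reaction_ids)
  if (length(bad)) stop("unknown flux label(s): ", paste(bad, collapse = ", "))
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    s <- scenarios[i, , drop = FALSE]
    meas <- to_measurements(s, model, full_band = cfg$full_band,
                            ref_band = cfg$ref_band,
                            ref_possibility = cfg$ref_possibility,
                            zero_floor = cfg$zero_floor)
    v <- max_possibility(model, meas)$v_mp[fluxes]
    out <- data.frame(id = s$id, stringsAsFactors = FALSE)
    for (f in fluxes) out[[f]] <- unname(v[f])
    for (f in fluxes) {
      out[[paste0("sign_", f)]] <-
        if (v[f] > tol) "+" else if (v[f] < -tol) "-" else "0"
    }
    out
  })
  do.call(rbind, rows)
}

#' Serialise a validation report to TSV files
#'
#' Writes `scenario_consistency.tsv`, `yields.tsv`, `growth_prediction.tsv`
#' (and `battery.tsv` when present) into a directory; runs with identical
#' configuration produce byte-identical files.
#'
#' @param report a `validation_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(format(df, digits = 10, trim = TRUE), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(wr(report$scenario_table, "scenario_consistency.tsv"),
             wr(report$yield_table, "yields.tsv"),
             wr(report$growth_prediction, "growth_prediction.tsv"))
  if (!is.null(report$battery)) {
    bt <- do.call(rbind, lapply(report$battery, function(b) {
      data.frame(battery = b$battery, n = b$n,
                 fraction_rejected = b$fraction_rejected)
    }))
    paths <- c(paths, wr(bt, "battery.tsv"))
  }
  invisible(paths)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", nrow(x$scenario_table), "scenarios\n")
  print(x$scenario_table, digits = 3)
  if (!is.null(x$battery)) {
    for (b in x$battery) {
      cat(sprintf("battery %d (n = %d): %.1f%% rejected at pi < 0.1\n",
                  b$battery, b$n, 100 * b$fraction_rejected))
    }
  }
  invisible(x)
}
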