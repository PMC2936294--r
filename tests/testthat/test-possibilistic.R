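test_that("measurement shaping reproduces the stated possibility pattern", {
  m <- shape_measurement(1.0)
  ## ±20 % deviation has possibility 0.1; ±9.5 % has 0.5
  expect_equal(measurement_possibility(m, 1.20), 0.1, tolerance = 1e-9)
  expect_equal(measurement_possibility(m, 0.80), 0.1, tolerance = 1e-9)
  expect_equal(measurement_possibility(m, 1.095), 0.5, tolerance = 5e-3)
  ## slope alpha = ln(10) / 0.15 for a unit measurement
  expect_equal(m$alpha, log(10) / 0.15, tolerance = 1e-12)
  expect_equal(m$beta, m$alpha)
  ## full-possibility band
  expect_equal(measurement_possibility(m, 1.049), 1)
  ## zero measurements are floored, not degenerate
  z <- shape_measurement(0)
  expect_equal(z$scale, 0.05)
  expect_true(is.finite(z$alpha) && z$alpha > 0)
  expect_error(shape_measurement(1, full_band = 0.3, ref_band = 0.2),
               "full_band")
})

test_that("measurements taken from a feasible state have possibility one", {
  mod <- pichia()
  set.seed(51)
  v <- sample_feasible_flux(pichia_ems(), seed = 51)
  meas <- perturb_measurements(v, mod, rel_noise = 0)
  expect_equal(max_possibility(mod, meas)$pi, 1, tolerance = 1e-9)
  expect_equal(minimal_full_band(mod, meas), 0, tolerance = 1e-8)
})

test_that("possibility is monotone under band widening and measurement removal", {
  mod <- pichia()
  sc <- scenarios_tab()
  for (id in c("A3", "B3")) {
    s <- sc[sc$id == id, ]
    meas <- to_measurements(s, mod)
    pi0 <- max_possibility(mod, meas)$pi
    wide <- to_measurements(s, mod, full_band = 0.10)
    expect_gte(max_possibility(mod, wide)$pi + 1e-9, pi0)
    softer <- to_measurements(s, mod, ref_possibility = 0.3)
    expect_gte(max_possibility(mod, softer)$pi + 1e-9, pi0)
    drop1 <- meas[-1, ]
    attr(drop1, "C") <- attr(meas, "C")[-1, , drop = FALSE]
    class(drop1) <- class(meas)
    expect_gte(max_possibility(mod, drop1)$pi + 1e-9, pi0)
  }
})

test_that("flux intervals propagate a measured uptake along a chain", {
  mod <- chain_model_exchange()
  meas <- possibilistic_measurements(mod, c(substrate = 1.0))
  mp <- max_possibility(mod, meas)
  expect_equal(mp$pi, 1)
  ## the chain forces efflux == uptake; at gamma the interval equals the
  ## band the measurement possibility assigns (1-d.o.f. closed form):
  ## half-width 0.05 + ln(1/gamma)/alpha around 1.0
  g <- 0.5
  iv <- flux_interval(mod, meas, "product", g)
  hw <- 0.05 + log(1 / g) / (log(10) / 0.15)
  expect_equal(iv$lower, 1 - hw, tolerance = 1e-6)
  expect_equal(iv$upper, 1 + hw, tolerance = 1e-6)
  expect_equal(iv$most_possible, 1, tolerance = 1e-9)
})

test_that("intervals are nested across gamma levels", {
  mod <- pichia()
  sc <- scenarios_tab()
  for (id in c("D1", "A4")) {
    s <- sc[sc$id == id, ]
    meas <- to_measurements(s, mod)
    for (fl in c("v02", "v34", "biomass")) {
      last <- NULL
      for (g in c(0.8, 0.5, 0.1)) {
        iv <- flux_interval(mod, meas, fl, g)
        expect_false(iv$empty)
        expect_lte(iv$lower, iv$most_possible + 1e-6)
        expect_gte(iv$upper, iv$most_possible - 1e-6)
        if (!is.null(last)) {
          ## lowering gamma can only widen the interval
          expect_lte(iv$lower, last$lower + 1e-7)
          expect_gte(iv$upper, last$upper - 1e-7)
        }
        last <- iv
      }
    }
  }
})

test_that("absolute intervals flag emptiness when gamma exceeds pi", {
  mod <- pichia()
  s <- scenarios_tab()[scenarios_tab()$id == "A4", ]
  meas <- to_measurements(s, mod)
  pi_a4 <- max_possibility(mod, meas)$pi
  expect_lt(pi_a4, 0.5)
  iv <- flux_interval(mod, meas, "biomass", 0.5, conditional = FALSE)
  expect_true(iv$empty)
  iv2 <- flux_interval(mod, meas, "biomass", 0.5, conditional = TRUE)
  expect_false(iv2$empty)
})

test_that("full possibility is equivalent to a minimal band within 5 %", {
  mod <- pichia()
  sc <- scenarios_tab()
  for (i in seq_len(nrow(sc))) {
    meas <- to_measurements(sc[i, ], mod)
    pi <- max_possibility(mod, meas)$pi
    b <- minimal_full_band(mod, meas)
    expect_equal(pi >= 1 - 1e-6, b <= 0.05 + 1e-6, info = sc$id[i])
  }
})

test_that("leave-one-out estimation recovers a toy efflux from its uptake", {
  mod <- chain_model_exchange()
  meas <- possibilistic_measurements(mod, c(substrate = 2.0, product = 2.0))
  est <- estimate_excluded_flux(mod, meas, "product")
  expect_equal(est$most_possible, 2.0, tolerance = 1e-8)
  expect_equal(nrow(est$intervals), 3L)
})

test_that("parameter recovery: truth lies in every gamma interval at 5 % noise", {
  mod <- pichia()
  ems <- pichia_ems()
  set.seed(606)
  for (k in 1:20) {
    v <- sample_feasible_flux(ems)
    meas <- perturb_measurements(v, mod, rel_noise = 0.05)
    mp <- max_possibility(mod, meas)
    expect_equal(mp$pi, 1, tolerance = 1e-7)
    truth_mu <- drop(exchange_functionals(mod, "biomass") %*% v)
    iv <- flux_interval(mod, meas, "biomass", 0.8)
    expect_true(iv$lower - 1e-7 <= truth_mu && truth_mu <= iv$upper + 1e-7)
  }
})
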