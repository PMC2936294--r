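test_that("the shipped datasets match the published transcription", {
  sc <- scenarios_tab()
  expect_equal(nrow(sc), 11L)
  expect_equal(sc$id, c("D1", paste0("A", 1:4), paste0("B", 1:3), paste0("C", 1:3)))
  d1 <- sc[sc$id == "D1", ]
  expect_equal(c(d1$mu, d1$q_glu, d1$our, d1$cpr), c(3.86, 0.97, 2.02, 2.07))
  a4 <- sc[sc$id == "A4", ]
  expect_equal(c(a4$q_met, a4$q_p), c(2.33, 0.024))
  ## transcription checksum over all numeric cells
  num <- as.matrix(sc[, c("mu", "q_glu", "q_gly", "q_met", "q_et",
                          "our", "cpr", "q_p")])
  expect_equal(sum(num), 139.317, tolerance = 1e-6)
  expect_true(all(num >= 0))
})

test_that("scenario rows convert to complete measurement sets", {
  mod <- pichia()
  sc <- scenarios_tab()
  meas <- to_measurements(sc[sc$id == "D1", ], mod)
  expect_equal(nrow(meas), 7L)
  expect_equal(meas$w[meas$quantity == "biomass"], 3.86)
  ## zero rates are retained with floored scales
  expect_equal(meas$scale[meas$quantity == "ethanol"], 0.05)
  ## round-trip: measurement values reproduce the scenario columns
  vals <- scenario_values(sc[sc$id == "B2", ])
  m2 <- to_measurements(sc[sc$id == "B2", ], mod)
  expect_equal(stats::setNames(m2$w, m2$quantity), vals)
  expect_error(to_measurements(sc[1, ], mod, include_qp = TRUE),
               "protein")
})

test_that("experimental yields reproduce the published arithmetic", {
  sc <- scenarios_tab()
  y <- vapply(seq_len(nrow(sc)),
              function(i) experimental_yield(sc[i, ]), numeric(1))
  names(y) <- sc$id
  ## published values at printed (2-decimal) precision; half a final digit of
  ## slack covers the table's own rounding (e.g. A1: 1.88/1.09 = 1.7248,
  ## printed as 1.73)
  want <- c(D1 = 3.98, A1 = 1.73, A2 = 1.31, A3 = 0.77, A4 = 0.70,
            B1 = 2.24, B3 = 1.26)
  for (id in names(want)) {
    expect_lt(abs(y[[id]] - want[[id]]), 0.0075, label = id)
  }
  zero <- sc[1, ]; zero$q_glu <- zero$q_gly <- zero$q_met <- 0
  expect_error(experimental_yield(zero), "no substrate uptake")
})

test_that("no experimental yield violates its theoretical maximum", {
  ems <- pichia_ems()
  sc <- scenarios_tab()
  for (i in seq_len(nrow(sc))) {
    cmp <- yield_vs_theoretical(sc[i, ], ems)
    expect_false(is.na(cmp$max_theoretical), info = sc$id[i])
    expect_false(cmp$violated, info = sc$id[i])
  }
})
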