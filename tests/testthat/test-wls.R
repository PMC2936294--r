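test_that("phi vanishes exactly for feasible measurements", {
  mod <- pichia()
  v <- sample_feasible_flux(pichia_ems(), seed = 71)
  C <- exchange_functionals(mod)
  vals <- stats::setNames(drop(C %*% v), rownames(C))
  r <- wls_residual(mod, vals)
  expect_lt(r$phi, 1e-7)
})

test_that("equality-only phi matches the normal-equation projection oracle", {
  ## fully reversible chain: no inequality constraints bind, so the optimum
  ## is the weighted projection onto the nullspace, solvable in closed form
  S <- matrix(c(-1, 0,
                1, -1,
                0, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("Sx", "A", "Px"), c("up", "out")))
  mod <- metabolic_model(S, reversible = c(TRUE, TRUE),
                         internal = c(FALSE, TRUE, FALSE),
                         exchange_map = data.frame(
                           quantity = c("substrate", "product"),
                           metabolite = c("Sx", "Px"),
                           direction = c("uptake", "production"),
                           stringsAsFactors = FALSE))
  w <- c(substrate = 1.0, product = 1.4)
  r <- wls_residual(mod, w, rel_sd = 0.10)
  ## nullspace is span(1,1): fit v = t*(1,1); minimise sum((w_k - t)^2 / s_k^2)
  s2 <- (0.10 * abs(w))^2
  t_hat <- sum(w / s2) / sum(1 / s2)
  phi_oracle <- sum((w - t_hat)^2 / s2)
  expect_equal(r$phi, phi_oracle, tolerance = 1e-6)
  expect_equal(unname(r$v_hat), c(t_hat, t_hat), tolerance = 1e-6)
  expect_equal(r$active_inequalities, 0L)
  expect_false(is.na(r$chisq_ref))
})

test_that("phi is invariant under common rescaling of all measurements", {
  mod <- pichia()
  s <- scenarios_tab()[scenarios_tab()$id == "A3", ]
  vals <- scenario_values(s)
  phi1 <- wls_residual(mod, vals, zero_floor = 0.05)$phi
  phi2 <- wls_residual(mod, 10 * vals, zero_floor = 0.5)$phi
  expect_equal(phi1, phi2, tolerance = 1e-6)
})

test_that("removing irreversibility constraints never increases phi", {
  mod <- pichia()
  relaxed <- metabolic_model(mod$S, reversible = rep(TRUE, 44),
                             internal = mod$internal, carbons = mod$carbons,
                             exchange_map = mod$exchange_map)
  for (id in c("A4", "B3", "C3")) {
    s <- scenarios_tab()[scenarios_tab()$id == id, ]
    vals <- scenario_values(s)
    expect_lte(wls_residual(relaxed, vals)$phi,
               wls_residual(mod, vals)$phi + 1e-7, label = id)
  }
})

test_that("phi and the possibilistic degree rank the datasets concordantly", {
  mod <- pichia()
  sc <- scenarios_tab()
  phis <- pis <- numeric(nrow(sc))
  for (i in seq_len(nrow(sc))) {
    phis[i] <- wls_residual(mod, scenario_values(sc[i, ]))$phi
    pis[i] <- max_possibility(mod, to_measurements(sc[i, ], mod))$pi
  }
  rho <- stats::cor(phis, -log(pmax(pis, 1e-12)), method = "spearman")
  expect_gt(rho, 0.5)
})
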