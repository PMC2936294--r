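test_that("enumeration matches the exhaustive support-subset oracle on random toys", {
  set.seed(4004)
  for (trial in 1:40) {
    mod <- random_toy_model(sample(2:4, 1), sample(3:7, 1))
    got <- enumerate_ems(mod)$modes
    want <- oracle_ems(mod)
    expect_identical(canon_modes(got), canon_modes(want),
                     info = paste("trial", trial))
  }
})

test_that("hand-verified toy networks have their known mode counts", {
  for (nm in names(toy_networks())) {
    toy <- toy_networks()[[nm]]
    ems <- enumerate_ems(toy$model)
    expect_equal(nrow(ems$modes), toy$n_ems, info = nm)
    expect_identical(canon_modes(ems$modes), canon_modes(oracle_ems(toy$model)),
                     info = nm)
  }
})

test_that("an irreversible chain has exactly one mode, the unit path", {
  ems <- enumerate_ems(chain_model())
  expect_equal(nrow(ems$modes), 1L)
  v <- ems$modes[1, ]
  expect_equal(unname(v / max(v)), c(1, 1, 1))
})

test_that("every shipped-model mode is a steady state with minimal support", {
  mod <- pichia()
  ems <- pichia_ems()
  V <- ems$modes
  for (i in seq_len(nrow(V))) {
    expect_true(check_steady_state(mod, V[i, ], tol = 1e-8)$ok)
  }
  ## pairwise support minimality
  supp <- abs(V) > 1e-9
  n_modes <- nrow(supp)
  for (i in seq_len(n_modes)) {
    others <- setdiff(seq_len(n_modes), i)
    subset_of_i <- vapply(others, function(j) {
      all(!supp[j, ] | supp[i, ]) && sum(supp[j, ]) < sum(supp[i, ])
    }, logical(1))
    expect_false(any(subset_of_i), info = paste("mode", i))
  }
})

test_that("the mode set is invariant under reaction permutation", {
  mod <- pichia()
  set.seed(99)
  perm <- sample(44)
  pm <- metabolic_model(mod$S[, perm], reversible = mod$reversible[perm],
                        internal = mod$internal, carbons = mod$carbons,
                        exchange_map = mod$exchange_map)
  ems1 <- enumerate_ems(mod)$modes
  ems2 <- enumerate_ems(pm)$modes
  ## un-permute and compare as sets
  ems2_back <- ems2[, order(perm), drop = FALSE]
  expect_identical(canon_modes(ems1), canon_modes(ems2_back))
})

test_that("yields respect carbon conservation and the per-Cmol bound", {
  ems <- pichia_ems()
  mac <- ems$macro
  carb <- c(glucose = 6, glycerol = 3, methanol = 1, ethanol = 2,
            o2 = 0, co2 = 1, biomass = 1)
  imbalance <- mac[, names(carb)] %*% carb
  expect_lt(max(abs(imbalance)), 1e-7)
  growth <- which(ems$category$produces_biomass)
  for (i in growth) {
    expect_lte(em_yield(ems, i, basis = "per_cmol"), 1 + 1e-9)
  }
})

test_that("methanol modes have identical per-mol and per-Cmol yields", {
  ems <- pichia_ems()
  idx <- which(ems$category$produces_biomass & ems$category$uses_methanol &
                 !ems$category$uses_glucose & !ems$category$uses_glycerol)
  for (i in idx) {
    expect_equal(em_yield(ems, i, "per_mol"), em_yield(ems, i, "per_cmol"),
                 tolerance = 1e-9)
  }
})

test_that("yield errors are raised for substrate-free modes", {
  ems <- enumerate_ems(chain_model())   # no exchange quantities at all
  expect_error(em_yield(ems, 1), "no carbon substrate")
})

test_that("the enumeration cap raises an explicit resource error", {
  expect_error(enumerate_ems(pichia(), max_modes = 10L), "exceeded the configured cap")
})
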