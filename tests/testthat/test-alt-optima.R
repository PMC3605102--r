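toy <- toy_network()
toy_prob <- imat_problem(toy$model, toy$calls)
toy_ens <- explore_optima(toy_prob)

test_that("every retained solution independently rescores to the optimum", {
  expect_gt(length(toy_ens$solutions), 0L)
  for (sol in toy_ens$solutions) {
    expect_equal(agreement_score(toy_prob, sol$flux), toy_ens$score)
  }
  # provenance covers off/forward for every reaction plus the baseline
  prov <- toy_ens$provenance
  expect_equal(sum(prov$modulation == "none"), 1L)
  expect_equal(sum(prov$modulation == "off"), 10L)
  expect_equal(sum(prov$modulation == "forward"), 10L)
  # the toy is irreversible, so no reverse modulations
  expect_equal(sum(prov$modulation == "reverse"), 0L)
  # modulation failures are recorded, not fatal
  expect_true(all(prov$outcome %in% c("retained", "suboptimal",
                                      "infeasible")))
})

test_that("frequency classification matches the definitions", {
  freq <- classify_frequencies(toy_ens)
  n <- ncol(toy_ens$flux)
  act <- abs(toy_ens$flux) > 1e-6
  expect_setequal(freq$HFR, rownames(act)[rowSums(act) == n])
  expect_setequal(freq$ZFR, rownames(act)[rowSums(act) == 0])
  expect_length(intersect(freq$HFR, freq$ZFR), 0L)
  # biomass is forced in every solve, so it is always high-frequency
  expect_true(biomass_id(toy$model) %in% freq$HFR)
  # the toy's always-active backbone
  expect_setequal(freq$HFR, c("r1", "r3", "r5", "r6", "r9"))
  expect_equal(unique(freq$table$n_solutions), n)
})

test_that("a unique optimum yields HFR = active set, ZFR = complement", {
  # chain with all reactions highly expressed: the optimum is the full
  # chain, unique up to flux magnitude
  m <- chain_model(4)
  calls <- reaction_calls(reaction_ids(m), character())
  ens <- explore_optima(imat_problem(m, calls))
  freq <- classify_frequencies(ens)
  expect_setequal(freq$HFR, reaction_ids(m))
  expect_length(freq$ZFR, 0L)
  # single solution ensembles classify trivially
  one <- ens
  one$flux <- ens$flux[, 1L, drop = FALSE]
  one$solutions <- ens$solutions[1L]
  f1 <- classify_frequencies(one)
  expect_setequal(f1$HFR, active_reactions(ens$flux[, 1L]))
  expect_setequal(f1$ZFR,
                  setdiff(reaction_ids(m), active_reactions(ens$flux[, 1L])))
})

test_that("heuristic HFR/ZFR contain the exhaustive-oracle sets", {
  for (seed in c(11, 12, 13, 14)) {
    inst <- small_random_instance(seed)
    calls <- call_reactions(inst$model, inst$expression)
    prob <- imat_problem(inst$model, calls)
    ens <- explore_optima(prob)
    freq <- classify_frequencies(ens)
    oracle <- oracle_frequency_sets(prob, ens$score)
    # reactions active (inactive) in every true optimum must be so in the
    # subset of optima the modulation scheme visits
    expect_true(all(oracle$HFR %in% freq$HFR), info = paste("seed", seed))
    expect_true(all(oracle$ZFR %in% freq$ZFR), info = paste("seed", seed))
  }
})

test_that("exploration is deterministic and deduplication is componentwise", {
  ens2 <- explore_optima(toy_prob)
  f1 <- classify_frequencies(toy_ens)
  f2 <- classify_frequencies(ens2)
  expect_identical(f1$HFR, f2$HFR)
  expect_identical(f1$ZFR, f2$ZFR)
  expect_identical(toy_ens$distinct_count, ens2$distinct_count)
  # duplicated columns collapse
  mat <- cbind(a = c(1, 0), b = c(1, 2e-7), c = c(2, 0))
  expect_equal(examo:::count_distinct_columns(mat, 1e-6), 2L)
})
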