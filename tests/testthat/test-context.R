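test_that("core consistency check finds exactly the blocked core", {
  toy <- toy_network()$model
  expect_length(check_core_consistency(toy, c("r5", "r9")), 0L)
  expect_length(check_core_consistency(toy, character()), 0L)
  # removing the only producers of C blocks everything that needs C,
  # including r6, whose product D then has no remaining consumer
  cut <- drop_reactions(toy, c("r3", "r7"), drop_orphans = FALSE)
  blocked <- check_core_consistency(cut, c("r5", "r8", "r6"))
  expect_setequal(blocked, c("r5", "r8", "r6"))
})

test_that("greedy pruning keeps the unique path to the core", {
  # 6-reaction fixture: chain to biomass plus a removable side branch
  m <- metabolic_model(list(
    reaction("upt", c("S[c]" = 1), lb = -1000, ub = 1000),
    reaction("s1", c("S[c]" = -1, "I[c]" = 1), ub = 1000),
    reaction("s2", c("I[c]" = -1, "P[c]" = 1), ub = 1000),
    reaction("side", c("I[c]" = -1, "W[c]" = 1), ub = 1000),
    reaction("side_ex", c("W[c]" = -1), lb = -1000, ub = 1000),
    reaction("bio", c("P[c]" = -1), ub = 1000, is_biomass = TRUE)))
  for (seed in 0:3) {
    ctx <- mba_prune(m, core = "bio", seed = seed)
    expect_setequal(reaction_ids(ctx$model), c("upt", "s1", "s2", "bio"))
    expect_setequal(ctx$removed$id, c("side", "side_ex"))
    expect_length(check_core_consistency(ctx$model, "bio"), 0L)
  }
  # core = all reactions: identity
  all_ctx <- mba_prune(m, core = reaction_ids(m), seed = 1)
  expect_setequal(reaction_ids(all_ctx$model), reaction_ids(m))
  # inconsistent input is rejected up front
  broken <- drop_reactions(m, "s1", drop_orphans = FALSE)
  expect_error(mba_prune(broken, core = "bio"), "blocked")
})

test_that("context building respects the HFR/ZFR containments", {
  toy <- toy_network()
  prob <- imat_problem(toy$model, toy$calls)
  freq <- classify_frequencies(explore_optima(prob))
  ctx <- build_context_model(toy$model, freq, seed = 0)
  ids <- reaction_ids(ctx$model)
  # HFR subset context subset parent minus ZFR
  expect_true(all(freq$HFR %in% ids))
  expect_length(intersect(ids, freq$ZFR), 0L)
  expect_true(all(ids %in% reaction_ids(toy$model)))
  expect_length(check_core_consistency(ctx$model, freq$HFR), 0L)
  # ZFR deletion stages precede pruning stages in the removal log
  stages <- ctx$removed$stage
  expect_true(all(which(stages == "zfr") < min(c(which(stages == "pruned"),
                                                 Inf))))
})

test_that("pruned models are locally minimal for every seed", {
  toy <- toy_network()
  freq <- classify_frequencies(explore_optima(
    imat_problem(toy$model, toy$calls)))
  for (seed in 0:2) {
    ctx <- build_context_model(toy$model, freq, seed = seed)
    noncore <- setdiff(reaction_ids(ctx$model), freq$HFR)
    for (id in noncore) {
      smaller <- drop_reactions(ctx$model, id, drop_orphans = FALSE)
      expect_gt(length(check_core_consistency(smaller, freq$HFR)), 0L)
    }
  }
})

test_that("identical seeds give identical context models", {
  inst <- generate_synthetic(synthetic_spec(seed = 3, chain_len = 5,
                                            n_decoys = 2, n_bypasses = 1))
  calls <- call_reactions(inst$model, inst$expression)
  freq <- classify_frequencies(explore_optima(
    imat_problem(inst$model, calls)))
  c1 <- build_context_model(inst$model, freq, seed = 42)
  c2 <- build_context_model(inst$model, freq, seed = 42)
  expect_identical(reaction_ids(c1$model), reaction_ids(c2$model))
  expect_identical(c1$removed, c2$removed)
})

test_that("ZFR deletions that block the core raise a conflict error", {
  m <- chain_model(4)
  freq <- frequency_sets(HFR = c("bio", "s2"), ZFR = "s1")
  expect_error(build_context_model(m, freq), "blocks")
})
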