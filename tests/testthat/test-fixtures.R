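test_that("the toy reconstruction satisfies its structural constraints", {
  toy <- toy_network()
  m <- toy$model
  expect_length(m$reactions, 10L)
  expect_identical(reaction_ids(m), sprintf("r%d", 1:10))
  # exactly five classified reactions: {r2, r3, r5, r6, r7}
  expect_setequal(names(toy$calls$calls), c("r2", "r3", "r5", "r6", "r7"))
  # r3 is an OR of two genes, r7 an AND of two genes
  expect_equal(m$reactions$r3$gpr$root$op, "or")
  expect_length(m$reactions$r3$gpr$genes, 2L)
  expect_equal(m$reactions$r7$gpr$root$op, "and")
  expect_length(m$reactions$r7$gpr$genes, 2L)
  # carbon conservation across every internal reaction
  carbons <- c("A[e]" = 2, "B[e]" = 3, "C[c]" = 2, "D[c]" = 3,
               "E[c]" = 5, "G[c]" = 1)
  for (r in m$reactions) {
    if (r$is_exchange) next
    expect_equal(sum(r$stoich * carbons[names(r$stoich)]), 0,
                 info = r$id)
  }
  # two- and three-carbon substrates, five-carbon precursor demand
  expect_equal(names(m$reactions$r1$stoich), "A[e]")
  expect_equal(names(m$reactions$r2$stoich), "B[e]")
  expect_identical(biomass_id(m), "r9")
})

test_that("route enumeration matches hand-countable networks", {
  expect_equal(enumerate_flux_modes(chain_model(4))$n, 1L)
  modes <- enumerate_flux_modes(parallel_model())
  expect_equal(modes$n, 2L)
  supports <- lapply(modes$patterns, names)
  expect_true(any(vapply(supports, function(s) "p1" %in% s, logical(1))))
  expect_true(any(vapply(supports, function(s) "p2" %in% s, logical(1))))
  # size refusal for large models
  inst <- generate_synthetic(synthetic_spec(seed = 1, chain_len = 12,
                                            n_decoys = 4))
  expect_error(enumerate_flux_modes(inst$model, max_size = 20),
               "refuse|max_size")
})

test_that("a reversible reaction contributes direction-distinct routes", {
  # biomass needs both A and P; the reversible converter can supply either
  # from the other, so it appears forward in one route, backward in another
  m <- metabolic_model(list(
    reaction("exA", c("A[c]" = 1), lb = -1000, ub = 1000),
    reaction("exP", c("P[c]" = 1), lb = -1000, ub = 1000),
    reaction("conv", c("A[c]" = -1, "P[c]" = 1), lb = -1000, ub = 1000),
    reaction("bio", c("A[c]" = -1, "P[c]" = -1), ub = 1000,
             is_biomass = TRUE)))
  modes <- enumerate_flux_modes(m)
  expect_equal(modes$n, 3L)
  conv_dirs <- unlist(lapply(modes$patterns, function(p) p["conv"]))
  expect_setequal(unique(conv_dirs[!is.na(conv_dirs)]), c(1L, -1L))
  expect_true(all(vapply(modes$patterns, function(p) p[["bio"]] == 1L,
                         logical(1))))
})

test_that("the synthetic generator honours its contract", {
  spec <- synthetic_spec(seed = 9, chain_len = 6, n_decoys = 3,
                         n_bypasses = 2, frac_reversible = 0.3)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$model, b$model)
  expect_identical(a$expression, b$expression)
  # planted subnetwork is flux-consistent and contains biomass
  expect_true(biomass_id(a$model) %in% a$planted)
  expect_length(check_core_consistency(a$model, a$planted), 0L)
  # the generated model passes dead-end trimming unchanged
  trimmed <- trim_dead_ends(a$model)
  expect_length(attr(trimmed, "removed"), 0L)
  # planted genes called high, decoy genes low or neither (noise 0)
  planted_genes <- unlist(reaction_genes(a$model)[a$planted])
  expect_true(all(a$expression$calls[planted_genes] == 1L))
  decoy_genes <- unlist(reaction_genes(a$model)[a$decoys])
  expect_true(all(a$expression$calls[decoy_genes] %in% c(-1L, 0L)))
  expect_error(synthetic_spec(chain_len = 2), "chain_len")
})

test_that("a 30-reaction synthetic instance runs the full pipeline", {
  inst <- generate_synthetic(synthetic_spec(seed = 5, chain_len = 8,
                                            n_decoys = 4, decoy_len = 2,
                                            n_bypasses = 2))
  expect_gte(length(inst$model$reactions), 24L)
  fit <- examo(inst$model, inst$expression, seed = 1)
  expect_s3_class(fit, "examo")
  expect_true(all(fit$freq$HFR %in% inst$planted))
  expect_true(all(inst$planted %in% reaction_ids(fit$context$model)))
  expect_equal(fit$imat$score,
               length(fit$calls$rH) + length(fit$calls$rL))
})
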