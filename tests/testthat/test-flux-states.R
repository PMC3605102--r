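test_that("a fully forced chain reproduces the k * eps closed form", {
  for (k in c(3, 5, 8)) {
    m <- chain_model(k)
    st <- minimize_total_flux(m, hfr = reaction_ids(m), eps = 1)
    expect_equal(st$total_flux, k * 1, tolerance = 1e-6)
    expect_true(all(abs(st$flux - 1) < 1e-6))
  }
  # and scales with eps
  m <- chain_model(4)
  st <- minimize_total_flux(m, hfr = reaction_ids(m), eps = 2.5)
  expect_equal(st$total_flux, 4 * 2.5, tolerance = 1e-6)
})

test_that("forcing only biomass matches a parsimonious LP oracle", {
  toy <- toy_network()$model
  st <- minimize_total_flux(toy, hfr = character(), eps = 1)
  # oracle: all-irreversible network, fix v_bio = eps, minimize sum v
  ids <- reaction_ids(toy)
  b <- model_bounds(toy)
  lb <- b$lb; ub <- b$ub
  jb <- match("r9", ids)
  lb[jb] <- 1; ub[jb] <- 1
  S <- stoichiometric_matrix(toy)
  res <- examo:::milp_solve(examo:::milp_problem(
    rep(1, length(ids)), A = S, con_lb = rep(0, nrow(S)),
    con_ub = rep(0, nrow(S)), lb = lb, ub = ub))
  expect_true(res$success)
  expect_equal(st$total_flux, res$objective, tolerance = 1e-6)
})

test_that("flux states are balanced with all forced reactions active", {
  toy <- toy_network()
  freq <- classify_frequencies(explore_optima(
    imat_problem(toy$model, toy$calls)))
  ctx <- build_context_model(toy$model, freq, seed = 0)
  st <- minimize_total_flux(ctx$model, freq$HFR, eps = 1)
  S <- stoichiometric_matrix(ctx$model)
  expect_lte(max(abs(S %*% st$flux)), 1e-6 * max(1, max(abs(st$flux))))
  expect_gte(min(abs(st$flux[freq$HFR])), 1 - 1e-6)
  # dropping a forced reaction can only lower (or keep) the total
  for (drop in setdiff(freq$HFR, "r9")) {
    st2 <- minimize_total_flux(ctx$model, setdiff(freq$HFR, drop), eps = 1)
    expect_lte(st2$total_flux, st$total_flux + 1e-9)
  }
})

test_that("a reversible forced reaction is active in exactly one direction", {
  m <- metabolic_model(list(
    reaction("in", c("A[c]" = 1), lb = -1000, ub = 1000),
    reaction("conv", c("A[c]" = -1, "B[c]" = 1), lb = -1000, ub = 1000),
    reaction("bio", c("B[c]" = -1), ub = 1000, is_biomass = TRUE)))
  st <- minimize_total_flux(m, hfr = "conv", eps = 1)
  expect_gte(abs(st$flux[["conv"]]), 1 - 1e-6)
  # forcing reverse use: biomass on the A side instead
  m2 <- metabolic_model(list(
    reaction("in", c("B[c]" = 1), lb = -1000, ub = 1000),
    reaction("conv", c("A[c]" = -1, "B[c]" = 1), lb = -1000, ub = 1000),
    reaction("bio", c("A[c]" = -1), ub = 1000, is_biomass = TRUE)))
  st2 <- minimize_total_flux(m2, hfr = "conv", eps = 1)
  expect_lte(st2$flux[["conv"]], -(1 - 1e-6))
  # infeasible joint activation reports the first failing activation
  m3 <- set_bounds(m, "conv", lb = 0, ub = 0)
  expect_error(minimize_total_flux(m3, hfr = "conv"), "conv")
})

test_that("FBA biomass maximum behaves on bound-limited and broken chains", {
  m <- chain_model(3)
  expect_equal(as.numeric(fba_max_biomass(m)), 1000, tolerance = 1e-6)
  broken <- set_bounds(m, "upt", lb = 0, ub = 0)
  g <- fba_max_biomass(broken)
  expect_equal(as.numeric(g), 0, tolerance = 1e-9)
  expect_gt(as.numeric(fba_max_biomass(toy_network()$model)), 0)
})

test_that("gene deletions respect isoenzyme and complex logic", {
  m <- metabolic_model(list(
    reaction("upt", c("S[c]" = 1), lb = -1000, ub = 1000),
    reaction("iso", c("S[c]" = -1, "I[c]" = 1), ub = 1000,
             gpr = "g1 OR g2"),
    reaction("cplx", c("I[c]" = -1, "P[c]" = 1), ub = 1000,
             gpr = "g3 AND g4"),
    reaction("bio", c("P[c]" = -1), ub = 1000, is_biomass = TRUE)))
  # isoenzyme rescue: deleting one OR gene keeps the reaction open
  d1 <- single_gene_deletion(m, "g1")
  expect_false(d1$essential)
  expect_gt(d1$growth, 0)
  # complex loss: deleting one AND subunit closes the reaction
  d4 <- single_gene_deletion(m, "g4")
  expect_true(d4$essential)
  expect_lt(d4$growth, 1e-6)
  expect_error(single_gene_deletion(m, "nope"), "not in the model")
  # batched screen agrees with the single-gene calls
  screen <- predict_essential_genes(m)
  expect_setequal(screen$gene[screen$essential], c("g3", "g4"))
})

test_that("sensitivity and PPV follow the tp/fp/fn definitions", {
  r <- essentiality_metrics(c("a", "b"), c("a", "b"),
                            universe = c("a", "b", "c"))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$ppv, 1)
  r2 <- essentiality_metrics(c("a", "b", "c"), c("a", "d"),
                             universe = letters[1:6])
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(1L, 2L, 1L))
  expect_equal(r2$sensitivity, 0.5)
  expect_equal(r2$ppv, 1 / 3)
  expect_equal(sum(r2$table$class == "tn"), 2L)
  # excluded genes are removed from both sets before counting
  r3 <- essentiality_metrics(c("a", "b"), c("a", "c"),
                             universe = letters[1:4], excluded = "a")
  expect_equal(c(r3$tp, r3$fp, r3$fn), c(0L, 1L, 1L))
  expect_identical(r3$table$class[r3$table$gene == "a"], "excluded")
  # undefined metrics reported as NA
  r4 <- essentiality_metrics(character(), character(), universe = "a")
  expect_true(is.na(r4$sensitivity))
  expect_true(is.na(r4$ppv))
})

test_that("highly expressed genes work directly as a predictor baseline", {
  # the HEG baseline is plain set arithmetic over the same scorer
  set.seed(1)
  vals <- stats::setNames(stats::rnorm(40), sprintf("g%02d", 1:40))
  calls <- call_genes(vals, 0.15, 0.15)
  heg <- names(calls$calls)[calls$calls == 1L]
  observed <- sprintf("g%02d", 1:8)
  r <- essentiality_metrics(heg, observed, universe = names(vals))
  expect_equal(r$tp, length(intersect(heg, observed)))
  expect_equal(r$sensitivity, r$tp / length(observed))
})
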