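test_that("reaction and model constructors enforce the invariants", {
  expect_error(reaction("r", c(A = 1), lb = 2, ub = 1), "lb > ub")
  expect_error(reaction("r", numeric()), "non-empty")
  expect_error(reaction("r", c(A = 1, A = -1)), "duplicated metabolite")
  expect_error(metabolic_model(list(reaction("r", c(A = 1)),
                                    reaction("r", c(B = 1)))),
               "duplicate reaction ids")
  expect_error(metabolic_model(list(
    reaction("r1", c(A = 1), is_biomass = TRUE),
    reaction("r2", c(B = 1), is_biomass = TRUE))),
    "at most one reaction")
  # exchange flag is derived from single-entry stoichiometry
  m <- metabolic_model(list(reaction("ex", c("A[c]" = 1)),
                            reaction("int", c("A[c]" = -1, "B[c]" = 1))))
  expect_identical(exchange_ids(m), "ex")
  # compartment parsed from the id tag
  expect_equal(m$metabolites$compartment, c("c", "c"))
  expect_setequal(m$genes, character())
})

test_that("stoichiometric matrix has the documented layout", {
  m <- metabolic_model(list(
    reaction("r1", c(A = -1, B = 1)),
    reaction("r2", c(B = -2, C = 1))))
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(3L, 2L))
  expect_equal(S[, "r1"], c(A = -1, B = 1, C = 0))
  expect_equal(S[, "r2"], c(A = 0, B = -2, C = 1))
  # number of nonzeros equals the total number of stoichiometric entries
  expect_equal(sum(S != 0),
               sum(lengths(lapply(m$reactions, `[[`, "stoich"))))
  # the zero flux is balanced
  expect_equal(as.numeric(S %*% rep(0, 2)), rep(0, 3))
})

test_that("reaction equations parse and format with correct signs", {
  eq <- parse_reaction_equation("2 A[c] + B[c] -> C[e]")
  expect_equal(eq$stoich, c("A[c]" = -2, "B[c]" = -1, "C[e]" = 1))
  expect_false(eq$reversible)
  expect_true(parse_reaction_equation("A <=> B")$reversible)
  # exchange: one-sided equation
  ex <- parse_reaction_equation("-> A[c]")
  expect_equal(ex$stoich, c("A[c]" = 1))
  expect_equal(parse_reaction_equation("A[c] ->")$stoich, c("A[c]" = -1))
  # round trip through the formatter
  expect_equal(
    parse_reaction_equation(format_reaction_equation(eq$stoich))$stoich,
    eq$stoich)
  expect_error(parse_reaction_equation("A => B", row = 3),
               "row 3.*unknown arrow")
  expect_error(parse_reaction_equation("x A -> B"), "non-numeric coefficient")
  expect_error(parse_reaction_equation("A + -> B"), "empty term")
})

test_that("model CSV round-trips stoichiometry, bounds, GPRs and flags", {
  toy <- toy_network()$model
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_csv(toy, path)
  back <- read_model_csv(path)
  expect_equal(stoichiometric_matrix(back)[rownames(stoichiometric_matrix(toy)),
                                           reaction_ids(toy)],
               stoichiometric_matrix(toy), tolerance = 1e-9)
  expect_equal(model_bounds(back), model_bounds(toy))
  expect_identical(biomass_id(back), biomass_id(toy))
  for (id in reaction_ids(toy)) {
    g_toy <- toy$reactions[[id]]$gpr
    g_back <- back$reactions[[id]]$gpr
    expect_setequal(g_back$genes, g_toy$genes)
    if (length(g_toy$genes) > 0) {
      grid <- expand.grid(rep(list(c(0, 1)), length(g_toy$genes)))
      names(grid) <- g_toy$genes
      for (i in seq_len(nrow(grid))) {
        vals <- unlist(grid[i, , drop = FALSE])
        expect_equal(eval_gpr(g_back, vals), eval_gpr(g_toy, vals))
      }
    }
  }
})

test_that("CSV reading applies arrow-implied bounds and catches format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,equation,gpr,lb,ub",
               "r1,uptake,-> A[c],,0,1000",
               "r2,conv,A[c] <=> B[c],,,",
               "r3,demand biomass,B[c] ->,,,"), path)
  m <- read_model_csv(path)
  expect_true(m$reactions$r1$is_exchange)
  expect_null(m$reactions$r1$gpr$root)
  expect_equal(m$reactions$r2$lb, -1000)
  expect_equal(m$reactions$r2$ub, 1000)
  expect_equal(m$reactions$r3$lb, 0)
  # single name containing "biomass" is flagged when no column is present
  expect_identical(biomass_id(m), "r3")

  writeLines(c("id,name,equation,gpr,lb,ub",
               "r1,a,-> A[c],,,",
               "r1,b,A[c] ->,,,"), path)
  expect_error(read_model_csv(path), "row 2.*duplicate reaction id")
  writeLines(c("id,name,equation,gpr,lb,ub",
               "r1,a,A[c] >> B[c],,,"), path)
  expect_error(read_model_csv(path), "row 1")
})

test_that("call/expression/flux table formats round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  calls <- c(gA = 1L, gB = -1L, gC = 0L)
  write_calls_tsv(calls, path, id_col = "gene")
  expect_identical(read_calls_tsv(path), calls)
  writeLines(c("gene\tvalue", "gA\t2.5", "gB\t-0.1"), path)
  expect_equal(read_expression_tsv(path), c(gA = 2.5, gB = -0.1))
  # flux table suppresses near-zero entries
  toy <- toy_network()$model
  flux <- stats::setNames(rep(0, 10), reaction_ids(toy))
  flux[c("r1", "r3")] <- c(5, 1e-12)
  write_flux_tsv(toy, flux, path)
  tab <- utils::read.delim(path)
  expect_identical(tab$reaction, "r1")
})
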