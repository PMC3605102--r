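test_that("percentile calls produce the documented set sizes", {
  vals <- stats::setNames(seq_len(100), sprintf("g%03d", 1:100))
  calls <- call_genes(vals, 0.15, 0.15)
  expect_equal(sum(calls$calls == 1L), 15L)
  expect_equal(sum(calls$calls == -1L), 15L)
  expect_equal(sum(calls$calls == 0L), 70L)
  # top-ranked genes are the high ones
  expect_true(all(calls$calls[sprintf("g%03d", 86:100)] == 1L))
  expect_true(all(calls$calls[sprintf("g%03d", 1:15)] == -1L))

  # ceiling rule: 3 genes -> 1 high, 1 low, 1 neither
  c3 <- call_genes(c(a = 1, b = 2, c = 3), 0.15, 0.15)
  expect_equal(as.vector(table(factor(c3$calls, levels = -1:1))),
               c(1L, 1L, 1L))

  expect_warning(flat <- call_genes(c(a = 1, b = 1, c = 1)), "identical")
  expect_true(all(flat$calls == 0L))
  expect_error(call_genes(c(a = 1, b = 2), hi_frac = 0.6))
})

test_that("ties are broken deterministically by value then gene id", {
  vals <- c(z = 5, a = 5, m = 1, b = 3, c = 3)
  c1 <- call_genes(vals, 0.2, 0.2)
  c2 <- call_genes(vals[sample(names(vals))], 0.2, 0.2)
  expect_identical(c1$calls[sort(names(vals))], c2$calls[sort(names(vals))])
  expect_equal(c1$calls[["a"]], 1L)   # alphabetical tie-break at the top
})

test_that("15% cutoffs sit near one standard deviation on log-normal data", {
  set.seed(42)
  x <- stats::setNames(stats::rlnorm(20000, meanlog = 5, sdlog = 1),
                       sprintf("g%05d", 1:20000))
  calls <- call_genes(x, 0.15, 0.15)
  hi_cut <- min(log(x[calls$calls == 1L]))
  lo_cut <- max(log(x[calls$calls == -1L]))
  # qnorm(0.85) ~ 1.04 sd; allow generous sampling slack
  expect_equal(hi_cut, 5 + 1.04, tolerance = 0.02)
  expect_equal(lo_cut, 5 - 1.04, tolerance = 0.02)
})

test_that("reaction calls follow the complex and isoenzyme prose rules", {
  m <- metabolic_model(list(
    reaction("complex_lo", c(A = -1, B = 1), gpr = "hi AND lo"),
    reaction("complex_hi", c(A = -1, B = 1), gpr = "hi AND hi2"),
    reaction("iso_hi", c(A = -1, B = 1), gpr = "lo OR hi"),
    reaction("iso_lo", c(A = -1, B = 1), gpr = "lo OR lo2"),
    reaction("nested1", c(A = -1, B = 1),
             gpr = "(hi AND hi2) OR (lo AND mid)"),
    reaction("nested2", c(A = -1, B = 1), gpr = "(lo OR lo2) AND hi"),
    reaction("nogpr", c(A = -1, B = 1)),
    reaction("unmeasured", c(A = -1, B = 1), gpr = "mystery")))
  calls <- call_reactions(m, c(hi = 1, hi2 = 1, lo = -1, lo2 = -1, mid = 0))
  expect_setequal(calls$rH, c("complex_hi", "iso_hi", "nested1"))
  expect_setequal(calls$rL, c("complex_lo", "iso_lo", "nested2"))
  # reactions without GPR or with only unmeasured genes are neither
  expect_false(any(c("nogpr", "unmeasured") %in% c(calls$rH, calls$rL)))
  expect_length(intersect(calls$rH, calls$rL), 0L)
})

test_that("raising one gene call never lowers a reaction call", {
  rules <- c("a AND b", "a OR b", "(a AND b) OR (c AND d)",
             "(a OR b) AND (c OR d)", "a OR (b AND (c OR d))")
  set.seed(7)
  for (rule in rules) {
    genes <- gpr_genes(rule)
    for (rep in 1:20) {
      vals <- stats::setNames(sample(-1:1, length(genes), replace = TRUE),
                              genes)
      base <- eval_gpr(rule, vals)
      g <- sample(genes, 1)
      if (vals[[g]] == 1L) next
      raised <- vals
      raised[[g]] <- vals[[g]] + 1L
      expect_gte(eval_gpr(rule, raised), base)
    }
  }
})

test_that("pre-made ternary calls are accepted verbatim", {
  calls <- as_expression_calls(c(a = 1, b = -1, c = 0))
  expect_s3_class(calls, "expression_calls")
  expect_identical(calls$calls, c(a = 1L, b = -1L, c = 0L))
  expect_error(as_expression_calls(c(a = 2)))
})
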