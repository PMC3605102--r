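# Small fixture networks built in code.

# linear chain of k reactions: uptake -> M1 -> ... -> M_{k-1} -> biomass
chain_model <- function(k, bound = 1000) {
  stopifnot(k >= 2)
  rxns <- list(reaction("upt", c("M1[c]" = 1), lb = -bound, ub = bound))
  if (k > 2) {
    for (i in seq_len(k - 2)) {
      rxns <- c(rxns, list(reaction(
        sprintf("s%d", i),
        stats::setNames(c(-1, 1), sprintf("M%d[c]", c(i, i + 1))),
        lb = 0, ub = bound)))
    }
  }
  rxns <- c(rxns, list(reaction(
    "bio", stats::setNames(-1, sprintf("M%d[c]", k - 1)),
    lb = 0, ub = bound, is_biomass = TRUE)))
  metabolic_model(rxns, id = sprintf("chain%d", k))
}

# two parallel paths from one substrate to the biomass precursor
parallel_model <- function(bound = 1000) {
  metabolic_model(list(
    reaction("upt", c("S[c]" = 1), lb = -bound, ub = bound),
    reaction("p1", c("S[c]" = -1, "P[c]" = 1), ub = bound),
    reaction("p2", c("S[c]" = -1, "P[c]" = 1), ub = bound),
    reaction("bio", c("P[c]" = -1), ub = bound, is_biomass = TRUE)),
    id = "parallel")
}

# seeded random instance with at most 12 reactions, randomized topology,
# reversibility and call noise; returns the generate_synthetic() list
small_random_instance <- function(seed) {
  set.seed(seed)
  chain_len <- sample(3:5, 1L)
  n_byp <- sample(0:min(2L, chain_len - 2L), 1L)
  decoy_len <- sample(1:2, 1L)
  budget <- 12L - 2L - chain_len - n_byp
  n_decoys <- min(sample(0:2, 1L), budget %/% (decoy_len + 1L))
  spec <- synthetic_spec(seed = seed + 1000L, chain_len = chain_len,
                         n_decoys = n_decoys, decoy_len = decoy_len,
                         n_bypasses = n_byp,
                         frac_reversible = stats::runif(1, 0, 0.5),
                         noise = stats::runif(1, 0, 0.4))
  generate_synthetic(spec)
}

write_toy_files <- function(dir) {
  toy <- toy_network()
  model_csv <- file.path(dir, "toy.csv")
  expr_tsv <- file.path(dir, "toy_expr.tsv")
  write_model_csv(toy$model, model_csv)
  utils::write.table(
    data.frame(gene = names(toy$expression$calls),
               value = as.integer(toy$expression$calls)),
    expr_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(model = model_csv, expr = expr_tsv, toy = toy)
}
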