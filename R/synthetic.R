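# Seeded synthetic networks with a planted active subnetwork.
#
# The generator emulates the situation the method is designed for: a
# flux-consistent model in which one biomass-producing subnetwork (a linear
# backbone with optional bypasses) is transcriptionally "on" while decoy
# branches are "off".  Gene calls are +1 on the planted reactions' genes and
# -1 on a sampled subset of decoy genes, with optional sign-flip noise.

#' Specify a synthetic network
#'
#' @param seed integer seed controlling topology, GPR assignment and calls.
#' @param chain_len number of reactions in the planted backbone (default 8).
#' @param n_decoys number of decoy branches hanging off the backbone
#'   (default 4); their genes are candidates for lowly-expressed calls.
#' @param decoy_len reactions per decoy branch before its exchange
#'   (default 2).
#' @param n_bypasses number of two-step bypasses across the backbone
#'   (default 2); bypasses carry no genes and create alternative optima.
#' @param frac_reversible fraction of backbone reactions made reversible
#'   (default 0.2); decoy steps stay irreversible so decoy exchanges cannot
#'   act as substrate sources.
#' @param noise probability that a gene call flips sign (default 0).
#' @param lo_prob probability that a decoy gene is called -1 rather than 0
#'   (default 0.8).
#' @param bound bound magnitude for all exchanges (default 1000).
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, chain_len = 8L, n_decoys = 4L,
                           decoy_len = 2L, n_bypasses = 2L,
                           frac_reversible = 0.2, noise = 0,
                           lo_prob = 0.8, bound = 1000) {
  stopifnot(chain_len >= 3L, n_decoys >= 0L, decoy_len >= 1L,
            n_bypasses >= 0L, frac_reversible >= 0, frac_reversible <= 1,
            noise >= 0, noise <= 1, bound > 0)
  if (n_bypasses > chain_len - 2L) {
    stop("synthetic_spec: at most chain_len - 2 bypasses fit", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), chain_len = as.integer(chain_len),
                 n_decoys = as.integer(n_decoys),
                 decoy_len = as.integer(decoy_len),
                 n_bypasses = as.integer(n_bypasses),
                 frac_reversible = frac_reversible, noise = noise,
                 lo_prob = lo_prob, bound = bound),
            class = "synthetic_spec")
}

#' Generate a synthetic model with a planted active subnetwork
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (a `metabolic_model`, exchanges already open at
#'   the spec's bound), `expression` (gene-level `expression_calls`),
#'   `planted` (reaction ids of the planted active subnetwork, including
#'   uptake and biomass), and `decoys` (reaction ids of the decoy branches).
#'   Identical specs (same seed) generate identical output.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  L <- spec$chain_len
  B <- spec$bound
  rxns <- list()
  gene_call <- integer()           # intended (noise-free) call per gene
  new_gpr <- function(prefix, call) {
    # some reactions get a two-gene complex or isoenzyme pair
    kind <- sample(c("single", "and", "or"), 1L, prob = c(0.5, 0.25, 0.25))
    gs <- if (kind == "single") prefix else paste0(prefix, c("x", "y"))
    for (g in gs) gene_call[[g]] <<- call
    if (kind == "single") gs
    else paste(gs, collapse = if (kind == "and") " and " else " or ")
  }

  # planted backbone: uptake -> M1 -> ... -> ML -> biomass
  rxns <- c(rxns, list(reaction("upt", c("M1[c]" = 1), lb = -B, ub = B,
                                name = "substrate exchange")))
  rev_flags <- stats::runif(L) < spec$frac_reversible
  for (i in seq_len(L)) {
    from <- sprintf("M%d[c]", i)
    to <- sprintf("M%d[c]", i + 1L)
    rxns <- c(rxns, list(reaction(
      sprintf("chain%d", i),
      stats::setNames(c(-1, 1), c(from, to)),
      lb = if (rev_flags[i]) -B else 0, ub = B,
      gpr = new_gpr(sprintf("gC%d", i), 1L),
      name = sprintf("backbone step %d", i))))
  }
  rxns <- c(rxns, list(reaction("biomass",
                                stats::setNames(-1, sprintf("M%d[c]", L + 1L)),
                                lb = 0, ub = B, is_biomass = TRUE,
                                name = "biomass demand")))
  planted <- c("upt", sprintf("chain%d", seq_len(L)), "biomass")

  # bypasses: M_i -> M_{i+2}, gene-free, create alternative optima
  if (spec$n_bypasses > 0L) {
    starts <- sort(sample(seq_len(L - 1L), spec$n_bypasses))
    for (k in seq_along(starts)) {
      i <- starts[k]
      rxns <- c(rxns, list(reaction(
        sprintf("bypass%d", k),
        stats::setNames(c(-1, 1), sprintf("M%d[c]", c(i, i + 2L))),
        lb = 0, ub = B, name = sprintf("bypass %d->%d", i, i + 2L))))
    }
  }

  # decoy branches: M_i -> D... -> exchange, genes candidate lowly expressed
  decoys <- character()
  if (spec$n_decoys > 0L) {
    at <- sample(seq_len(L), spec$n_decoys, replace = TRUE)
    for (k in seq_len(spec$n_decoys)) {
      prev <- sprintf("M%d[c]", at[k])
      for (s in seq_len(spec$decoy_len)) {
        met <- sprintf("D%d_%d[c]", k, s)
        id <- sprintf("decoy%d_%d", k, s)
        call <- if (stats::runif(1) < spec$lo_prob) -1L else 0L
        # decoy steps are kept irreversible (pointing away from the
        # backbone) so decoy exchanges cannot act as substrate sources
        rxns <- c(rxns, list(reaction(
          id, stats::setNames(c(-1, 1), c(prev, met)),
          lb = 0, ub = B,
          gpr = new_gpr(sprintf("gD%d_%d", k, s), call),
          name = sprintf("decoy branch %d step %d", k, s))))
        decoys <- c(decoys, id)
        prev <- met
      }
      ex_id <- sprintf("decoy%d_ex", k)
      rxns <- c(rxns, list(reaction(ex_id, stats::setNames(-1, prev),
                                    lb = -B, ub = B,
                                    name = sprintf("decoy %d exchange", k))))
      decoys <- c(decoys, ex_id)
    }
  }

  calls <- unlist(gene_call)
  flip <- stats::runif(length(calls)) < spec$noise
  calls[flip] <- -calls[flip]
  model <- metabolic_model(rxns, id = sprintf("synthetic_seed%d", spec$seed))
  list(model = model,
       expression = as_expression_calls(calls),
       planted = planted, decoys = decoys)
}
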