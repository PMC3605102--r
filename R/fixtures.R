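# Test fixtures and small-network oracles: the ten-reaction toy network,
# exhaustive enumeration of support-minimal flux routes (the operational
# reading of "flux distribution" under which the toy's printed counts are
# well defined), enumeration of optimal activity patterns, and a seeded
# synthetic-network generator with a planted active subnetwork.

#' Enumerate support-minimal biomass-producing flux routes
#'
#' Enumerates every support-minimal, steady-state, direction-respecting flux
#' pattern that produces through the biomass reaction, by a MILP with binary
#' support indicators and no-good cuts: repeatedly find a minimum-cardinality
#' active pattern, record it, and exclude it (and its supersets) with an
#' integer cut until the MILP becomes infeasible.  A reversible reaction
#' used forward and used backward gives two different routes.  Each route is
#' verified minimal: zeroing any one active reaction within the route's
#' support leaves no feasible biomass-producing flux.
#'
#' @param model a `metabolic_model` with finite bounds and a designated
#'   biomass reaction.
#' @param max_size refuse models with more than this many reactions
#'   (default 20; the enumeration is exponential).
#' @param act activation threshold defining "carries flux" (default 1.0).
#' @param max_modes safety cap on the number of routes (default 512).
#' @return a `flux_modes` object: list with `patterns` (list of named sign
#'   vectors, +1 forward / -1 reverse, over the active reactions only),
#'   `fluxes` (one witness flux vector per route) and `n`.
#' @export
enumerate_flux_modes <- function(model, max_size = 20, act = 1,
                                 max_modes = 512L) {
  stopifnot(inherits(model, "metabolic_model"))
  m <- length(model$reactions)
  if (m > max_size) {
    stop("enumerate_flux_modes: model has ", m, " reactions > max_size = ",
         max_size, "; the enumeration oracle is exponential and refuses ",
         "large models", call. = FALSE)
  }
  bio <- biomass_id(model)
  if (is.null(bio)) {
    stop("enumerate_flux_modes: no biomass reaction designated",
         call. = FALSE)
  }
  base <- flux_modes_milp(model, act)
  cuts <- list()
  patterns <- list()
  fluxes <- list()
  repeat {
    built <- add_pattern_cuts(base, cuts)
    res <- milp_solve(built)
    if (!res$success) break
    pat <- extract_pattern(base, res)
    patterns <- c(patterns, list(pat$signs))
    fluxes <- c(fluxes, list(pat$flux))
    cuts <- c(cuts, list(pat$cut))
    if (length(patterns) >= max_modes) {
      stop("enumerate_flux_modes: more than ", max_modes, " routes",
           call. = FALSE)
    }
  }
  verify_modes_minimal(base, patterns)
  structure(list(patterns = patterns, fluxes = fluxes,
                 n = length(patterns), act = act, biomass = bio),
            class = "flux_modes")
}

#' @export
print.flux_modes <- function(x, ...) {
  cat("<flux_modes> ", x$n, " support-minimal biomass-producing routes\n",
      sep = "")
  for (i in seq_len(x$n)) {
    s <- x$patterns[[i]]
    cat(sprintf("  %2d: %s\n", i,
                paste0(names(s), ifelse(s < 0, "(rev)", ""),
                       collapse = " ")))
  }
  invisible(x)
}

# Variable layout for the route-enumeration MILP: v+ (m), v- (m),
# a+ (m binaries), a- (binaries for reversibles only).
flux_modes_milp <- function(model, act, biomass_lb = NULL) {
  ids <- reaction_ids(model)
  m <- length(ids)
  b <- model_bounds(model)
  if (any(is.infinite(b$lb)) || any(is.infinite(b$ub))) {
    stop("route enumeration requires finite bounds", call. = FALSE)
  }
  ubp <- pmax(b$ub, 0)
  ubm <- pmax(-b$lb, 0)
  rev_idx <- which(b$lb < 0)
  idx_ap <- 2L * m + seq_len(m)
  idx_am <- if (length(rev_idx) > 0L) 3L * m + seq_along(rev_idx)
            else integer()
  nv <- 3L * m + length(rev_idx)
  S <- stoichiometric_matrix(model)
  rows <- list(); rlb <- numeric(); rub <- numeric()
  add_row <- function(row, lo, hi) {
    rows[[length(rows) + 1L]] <<- row
    rlb[length(rlb) + 1L] <<- lo
    rub[length(rub) + 1L] <<- hi
  }
  for (i in seq_len(nrow(S))) {
    row <- numeric(nv)
    row[seq_len(m)] <- S[i, ]
    row[m + seq_len(m)] <- -S[i, ]
    add_row(row, 0, 0)
  }
  for (j in seq_len(m)) {
    row <- numeric(nv); row[j] <- 1; row[idx_ap[j]] <- -act
    add_row(row, 0, Inf)                       # v+ >= act a+
    row <- numeric(nv); row[j] <- 1; row[idx_ap[j]] <- -ubp[j]
    add_row(row, -Inf, 0)                      # v+ <= ubp a+
  }
  for (k in seq_along(rev_idx)) {
    j <- rev_idx[k]
    row <- numeric(nv); row[m + j] <- 1; row[idx_am[k]] <- -act
    add_row(row, 0, Inf)                       # v- >= act a-
    row <- numeric(nv); row[m + j] <- 1; row[idx_am[k]] <- -ubm[j]
    add_row(row, -Inf, 0)                      # v- <= ubm a-
    row <- numeric(nv); row[idx_ap[j]] <- 1; row[idx_am[k]] <- 1
    add_row(row, -Inf, 1)                      # one direction at a time
  }
  vlb <- rep(0, nv)
  vub <- c(ubp, ubm, rep(1, m), rep(1, length(rev_idx)))
  # irreversible reactions get no v- (capacity 0 closes it)
  jb <- match(biomass_id(model), ids)
  vlb[idx_ap[jb]] <- 1                         # biomass route must be active
  if (!is.null(biomass_lb)) vlb[jb] <- max(vlb[jb], biomass_lb)
  obj <- numeric(nv)
  obj[c(idx_ap, idx_am)] <- 1
  list(A = do.call(rbind, rows), rlb = rlb, rub = rub,
       vlb = vlb, vub = vub, obj = obj,
       integrality = c(integer(2L * m), rep(1L, m + length(rev_idx))),
       ids = ids, m = m, rev_idx = rev_idx,
       idx_ap = idx_ap, idx_am = idx_am)
}

add_pattern_cuts <- function(base, cuts) {
  A <- base$A; rlb <- base$rlb; rub <- base$rub
  for (cut in cuts) {
    row <- numeric(length(base$obj))
    row[cut$cols] <- 1
    A <- rbind(A, row)
    rlb <- c(rlb, -Inf)
    rub <- c(rub, length(cut$cols) - 1)
  }
  milp_problem(base$obj, A = A, con_lb = rlb, con_ub = rub,
               lb = base$vlb, ub = base$vub,
               integrality = base$integrality, maximize = FALSE)
}

extract_pattern <- function(base, res) {
  m <- base$m
  ap <- round(res$x[base$idx_ap])
  am <- stats::setNames(rep(0, m), NULL)
  if (length(base$rev_idx) > 0L) {
    am[base$rev_idx] <- round(res$x[base$idx_am])
  }
  flux <- stats::setNames(res$x[seq_len(m)] - res$x[m + seq_len(m)],
                          base$ids)
  active <- which(ap == 1 | am == 1)
  signs <- stats::setNames(ifelse(am[active] == 1, -1L, 1L),
                           base$ids[active])
  cols <- c(base$idx_ap[which(ap == 1)],
            base$idx_am[match(which(am == 1), base$rev_idx)])
  list(signs = signs, flux = flux, cut = list(cols = cols))
}

# each route, with any one active reaction forced off (support restricted to
# the route), must be infeasible; solved as one LP batch
verify_modes_minimal <- function(base, patterns) {
  if (length(patterns) == 0L) return(invisible(TRUE))
  probs <- list()
  for (pat in patterns) {
    for (drop in names(pat)) {
      vlb <- base$vlb; vub <- base$vub
      for (j in seq_len(base$m)) {
        id <- base$ids[j]
        in_fwd <- id %in% names(pat) && pat[[id]] > 0 && id != drop
        in_rev <- id %in% names(pat) && pat[[id]] < 0 && id != drop
        if (!in_fwd) vub[j] <- 0
        if (!in_rev) vub[base$m + j] <- 0
      }
      # biomass activity: a+ lower bound of 1 stays; relax binaries to their
      # implied fluxes by keeping indicator rows consistent
      probs <- c(probs, list(milp_problem(
        base$obj, A = base$A, con_lb = base$rlb, con_ub = base$rub,
        lb = vlb, ub = vub, integrality = base$integrality,
        maximize = FALSE)))
    }
  }
  res <- milp_solve_batch(probs)
  if (any(vapply(res, function(r) isTRUE(r$success), logical(1L)))) {
    stop("internal error: enumerated route is not support-minimal",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Enumerate all optimal activity patterns of an iMAT problem
#'
#' Enumerates the support-minimal biomass-producing routes of the problem's
#' model (at activation threshold `eps`), scores each route's activity
#' pattern against the rH/rL calls, and returns the routes attaining the
#' provably maximal agreement score of [solve_imat()].
#'
#' @param problem an [imat_problem()].
#' @param max_size size refusal limit passed to the route enumeration.
#' @return list with `score` (the optimum), `patterns` (optimal routes as
#'   sign vectors), `all_patterns`, `all_scores`.
#' @export
enumerate_optimal_patterns <- function(problem, max_size = 20) {
  stopifnot(inherits(problem, "imat_problem"))
  s_star <- solve_imat(problem)$score
  modes <- enumerate_flux_modes(problem$model, max_size = max_size,
                                act = problem$eps)
  scores <- vapply(modes$patterns, function(pat) {
    active <- names(pat)
    sum(problem$rH %in% active) + sum(!problem$rL %in% active)
  }, numeric(1L))
  list(score = s_star,
       patterns = modes$patterns[scores == s_star],
       all_patterns = modes$patterns,
       all_scores = as.integer(scores))
}

#' The ten-reaction toy network and its expression calls
#'
#' A small pathway synthesizing a five-carbon biomass precursor from a
#' two-carbon or a three-carbon substrate, with a gene-to-reaction mapping
#' in which r3 is catalyzed by either of two isoenzymes (OR) and r7 by a
#' two-subunit complex (AND).  Carbon is conserved by every internal
#' reaction.  The network supports exactly 8 support-minimal flux routes,
#' only 2 of which survive closing the two-carbon uptake; the maximal iMAT
#' agreement score is 4 (with the complex reaction r7 as the one
#' disagreement), attained by 3 of the 8 routes.
#'
#' @return list with `model` (a `metabolic_model`), `expression` (gene-level
#'   `expression_calls`) and `calls` (the derived `reaction_calls`).
#' @export
toy_network <- function() {
  rxns <- list(
    reaction("r1", c("A[e]" = 1), lb = 0, ub = 1000,
             name = "two-carbon substrate uptake"),
    reaction("r2", c("B[e]" = 1), lb = 0, ub = 1000, gpr = "g2",
             name = "three-carbon substrate uptake"),
    reaction("r3", c("A[e]" = -1, "C[c]" = 1), gpr = "g3a or g3b",
             name = "2C activation (isoenzymes)"),
    reaction("r4", c("C[c]" = -1, "G[c]" = -1, "D[c]" = 1),
             name = "1C salvage to 3C"),
    reaction("r5", c("C[c]" = -1, "D[c]" = -1, "E[c]" = 1), gpr = "g5",
             name = "condensation to 5C precursor"),
    reaction("r6", c("A[e]" = -2, "D[c]" = 1, "G[c]" = 1), gpr = "g6",
             name = "2C condensation to 3C"),
    reaction("r7", c("B[e]" = -1, "C[c]" = 1, "G[c]" = 1),
             gpr = "g7a and g7b", name = "3C cleavage (complex)"),
    reaction("r8", c("C[c]" = -2, "G[c]" = -1, "E[c]" = 1),
             name = "alternative 5C synthesis"),
    reaction("r9", c("E[c]" = -1), is_biomass = TRUE,
             name = "biomass precursor demand"),
    reaction("r10", c("G[c]" = -1), name = "one-carbon export"))
  model <- metabolic_model(rxns, id = "toy")
  expression <- as_expression_calls(c(
    g2 = -1L, g3a = 1L, g3b = -1L, g5 = 1L, g6 = 1L, g7a = 1L, g7b = 1L))
  list(model = model, expression = expression,
       calls = call_reactions(model, expression))
}
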