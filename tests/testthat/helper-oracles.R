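# Independent oracles used to cross-check the MILP implementations on small
# instances.  They share only the generic solver layer with the code under
# test; the formulations are constructed independently.

# Brute-force agreement-score oracle: enumerate every assignment of
# "satisfied" states over the classified reactions (rH: active forward /
# active backward / unsatisfied; rL: zero / unsatisfied), check each by LP
# feasibility, and return the best feasible score.
oracle_imat_score <- function(problem) {
  model <- problem$model
  ids <- reaction_ids(model)
  b <- model_bounds(model)
  eps <- problem$eps
  choices <- list()
  for (id in problem$rH) {
    j <- match(id, ids)
    opts <- c("fwd", "unsat")
    if (b$lb[j] <= -eps) opts <- c(opts, "rev")
    choices[[id]] <- opts
  }
  for (id in problem$rL) choices[[id]] <- c("zero", "unsat")
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  m <- length(ids)
  probs <- vector("list", nrow(grid))
  scores <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    extra_lb <- rep(-Inf, m); extra_ub <- rep(Inf, m)
    score <- 0L
    for (id in names(choices)) {
      j <- match(id, ids)
      st <- grid[[id]][g]
      if (st == "fwd") { extra_lb[j] <- eps; score <- score + 1L }
      if (st == "rev") { extra_ub[j] <- -eps; score <- score + 1L }
      if (st == "zero") {
        extra_lb[j] <- 0; extra_ub[j] <- 0; score <- score + 1L
      }
    }
    jb <- match(problem$biomass, ids)
    extra_lb[jb] <- max(extra_lb[jb], problem$biomass_min)
    scores[g] <- score
    probs[[g]] <- examo:::steady_state_lp(model, rep(0, m),
                                          extra_lb = extra_lb,
                                          extra_ub = extra_ub)
  }
  res <- examo:::milp_solve_batch(probs)
  feas <- vapply(res, function(r) isTRUE(r$success), logical(1L))
  if (!any(feas)) return(NA_integer_)
  max(scores[feas])
}

# Exhaustive HFR/ZFR oracle: a reaction is in the exhaustive HFR iff no
# optimal solution (score fixed at s_star) has it inactive, and in the
# exhaustive ZFR iff no optimal solution has it active (|v| >= delta in
# either direction).  One feasibility MILP per question, batched.
oracle_frequency_sets <- function(problem, s_star, delta = 1e-4) {
  model <- problem$model
  ids <- reaction_ids(model)
  b <- model_bounds(model)
  fix_score <- function(built) {
    p <- built$problem
    A <- rbind(p$A, p$obj)
    examo:::milp_problem(rep(0, length(p$obj)), A = A,
                         con_lb = c(p$con_lb, s_star),
                         con_ub = c(p$con_ub, s_star),
                         lb = p$lb, ub = p$ub,
                         integrality = p$integrality)
  }
  probs <- list(); tags <- list()
  for (id in ids) {
    j <- match(id, ids)
    variants <- list(off = c(0, 0),
                     fwd = c(delta, b$ub[j]))
    if (b$lb[j] < 0) variants$rev <- c(b$lb[j], -delta)
    for (v in names(variants)) {
      built <- examo:::imat_milp(problem,
                                 stats::setNames(list(variants[[v]]), id))
      probs <- c(probs, list(if (is.null(built)) NULL else fix_score(built)))
      tags <- c(tags, list(c(id, v)))
    }
  }
  solvable <- !vapply(probs, is.null, logical(1L))
  res <- vector("list", length(probs))
  res[solvable] <- examo:::milp_solve_batch(probs[solvable])
  feas <- vapply(seq_along(probs), function(k) {
    solvable[k] && isTRUE(res[[k]]$success)
  }, logical(1L))
  can <- data.frame(id = vapply(tags, `[`, "", 1L),
                    variant = vapply(tags, `[`, "", 2L),
                    feasible = feas, stringsAsFactors = FALSE)
  hfr <- vapply(ids, function(id) {
    !any(can$feasible[can$id == id & can$variant == "off"])
  }, logical(1L))
  zfr <- vapply(ids, function(id) {
    !any(can$feasible[can$id == id & can$variant %in% c("fwd", "rev")])
  }, logical(1L))
  list(HFR = ids[hfr], ZFR = ids[zfr])
}

# direct truth-table evaluation of a GPR string via R's own parser:
# AND/OR are replaced by & and |, gene ids by their logical values
oracle_gpr_eval <- function(text, values) {
  expr <- gsub("\\bAND\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bOR\\b", "|", expr, ignore.case = TRUE)
  for (g in names(values)) {
    expr <- gsub(paste0("\\b", g, "\\b"),
                 if (values[[g]] > 0) "TRUE" else "FALSE", expr)
  }
  as.numeric(eval(parse(text = expr)))
}
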