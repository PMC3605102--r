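# Environment-specific model extraction: delete the zero-frequency
# reactions, then greedily prune reactions outside the high-frequency core
# in seeded random order, keeping a removal only if every core reaction can
# still carry flux (MBA-style sweep repeated to a fixed point).

#' List core reactions blocked in a model
#'
#' Runs FVA restricted to the core reactions and returns those whose entire
#' feasible flux range lies within `(-tol, +tol)`.
#'
#' @param model a `metabolic_model`.
#' @param core character vector of core reaction ids (subset of the model).
#' @param tol activity tolerance (default 1e-6).
#' @return character vector of blocked core ids; empty when consistent.
#' @export
check_core_consistency <- function(model, core, tol = 1e-6) {
  core <- as.character(core)
  if (length(core) == 0L) return(character())
  stopifnot(all(core %in% reaction_ids(model)))
  fva <- flux_variability(model, reactions = core)
  blocked_reactions(fva, tol = tol)
}

#' Greedy MBA-style pruning outside a core set
#'
#' Iterates over non-core reactions in a seeded random order, tentatively
#' removing each; a removal is kept only if every core reaction can still
#' carry `|v| >= tol` in the reduced model.  Because deleting reactions only
#' shrinks the flux space, one sweep already reaches the fixed point where a
#' further sweep would remove nothing, so the result is locally minimal:
#' removing any remaining non-core reaction blocks some core reaction.
#'
#' @param model a `metabolic_model`, consistent with respect to `core`.
#' @param core character vector of core reaction ids to preserve.
#' @param seed integer seed for the removal order (default 0).
#' @param tol core activity tolerance (default 1e-6).
#' @return a `context_model`: list with `model` (the pruned
#'   `metabolic_model`), `core`, `removed` (data.frame id/stage in removal
#'   order) and `seed`.
#' @export
mba_prune <- function(model, core, seed = 0, tol = 1e-6) {
  core <- as.character(core)
  stopifnot(all(core %in% reaction_ids(model)))
  blocked <- check_core_consistency(model, core, tol = tol)
  if (length(blocked) > 0L) {
    stop("mba_prune: input model is inconsistent with the core; blocked: ",
         paste(blocked, collapse = ", "), call. = FALSE)
  }
  removed <- character()
  candidates <- with_seed(seed, sample(setdiff(reaction_ids(model), core)))
  for (id in candidates) {
    trial <- drop_reactions(model, id, drop_orphans = FALSE)
    if (length(check_core_consistency(trial, core, tol = tol)) == 0L) {
      model <- trial
      removed <- c(removed, id)
    }
  }
  # One sweep reaches the fixed point: removing reactions only shrinks the
  # flux space, so a candidate whose removal once blocked the core can never
  # become removable later; a second sweep would remove nothing.
  model <- drop_orphan_metabolites(model)
  structure(list(model = model, core = core,
                 removed = data.frame(id = removed,
                                      stage = rep("pruned", length(removed)),
                                      stringsAsFactors = FALSE),
                 seed = seed, tol = tol),
            class = "context_model")
}

#' Build an environment-specific context model
#'
#' Deletes the zero-frequency reactions, checks that every high-frequency
#' reaction remains flux-consistent, and prunes the remainder with
#' [mba_prune()].
#'
#' @param parent the parent `metabolic_model` (opened and trimmed).
#' @param freq a `frequency_sets` object (from [classify_frequencies()]).
#' @param seed integer seed for the pruning order (default 0).
#' @param tol core activity tolerance (default 1e-6).
#' @return a `context_model`; its `removed` table lists ZFR deletions first,
#'   then pruned reactions.
#' @export
build_context_model <- function(parent, freq, seed = 0, tol = 1e-6) {
  stopifnot(inherits(parent, "metabolic_model"))
  if (!all(c("HFR", "ZFR") %in% names(freq))) {
    stop("`freq` must carry HFR and ZFR sets", call. = FALSE)
  }
  hfr <- as.character(freq$HFR); zfr <- as.character(freq$ZFR)
  stopifnot(all(hfr %in% reaction_ids(parent)),
            all(zfr %in% reaction_ids(parent)))
  reduced <- if (length(zfr) > 0L) {
    drop_reactions(parent, zfr, drop_orphans = TRUE)
  } else parent
  blocked <- check_core_consistency(reduced, hfr, tol = tol)
  if (length(blocked) > 0L) {
    stop("build_context_model: deleting the ZFR blocks high-frequency ",
         "reactions: ", paste(blocked, collapse = ", "), call. = FALSE)
  }
  ctx <- mba_prune(reduced, hfr, seed = seed, tol = tol)
  ctx$removed <- rbind(data.frame(id = zfr,
                                  stage = rep("zfr", length(zfr)),
                                  stringsAsFactors = FALSE),
                       ctx$removed)
  ctx
}

#' @export
print.context_model <- function(x, ...) {
  cat("<context_model> ", length(x$model$reactions), " reactions (core ",
      length(x$core), "); removed ", sum(x$removed$stage == "zfr"),
      " ZFR + ", sum(x$removed$stage == "pruned"), " pruned; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

drop_orphan_metabolites <- function(model) {
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  mets <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  rownames(mets) <- NULL
  metabolic_model(model$reactions, metabolites = mets, id = model$id)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
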