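# Environment-agnostic preprocessing: open every exchange reaction so that
# any metabolite may be freely taken up or secreted (nutrient availability
# unknown), then remove dead-end reactions that can never carry flux, found
# by flux variability analysis (FVA), iterating to a flux-consistent model.

# shared steady-state LP scaffold: lb <= v <= ub, S v = 0
steady_state_lp <- function(model, obj, maximize = FALSE,
                            extra_lb = NULL, extra_ub = NULL) {
  S <- stoichiometric_matrix(model)
  b <- model_bounds(model)
  lb <- if (is.null(extra_lb)) b$lb else pmax(b$lb, extra_lb)
  ub <- if (is.null(extra_ub)) b$ub else pmin(b$ub, extra_ub)
  milp_problem(obj = obj, A = S, con_lb = rep(0, nrow(S)),
               con_ub = rep(0, nrow(S)), lb = lb, ub = ub,
               maximize = maximize)
}

#' Open all exchange reactions
#'
#' Sets the bounds of every exchange reaction to
#' `[-bound_magnitude, +bound_magnitude]`, enabling free uptake or secretion
#' of every boundary metabolite.  This models growth in an uncharacterized
#' environment and also guarantees finite bounds for the big-M constraints
#' of the downstream mixed-integer programs.
#'
#' @param model a `metabolic_model`.
#' @param bound_magnitude positive bound magnitude (default 1000, the
#'   conventional "effectively unbounded" value).
#' @return the model with rewritten exchange bounds; internal reactions are
#'   untouched.  A model without exchange reactions is returned unchanged
#'   with a warning.
#' @export
open_exchanges <- function(model, bound_magnitude = 1000) {
  stopifnot(bound_magnitude > 0)
  ex <- exchange_ids(model)
  if (length(ex) == 0L) {
    warning("model has no exchange reactions; returned unchanged")
    return(model)
  }
  set_bounds(model, ex, lb = -bound_magnitude, ub = bound_magnitude)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux over the
#' steady-state flux space `{S v = 0, lb <= v <= ub}`.  No growth constraint
#' is imposed, as appropriate for dead-end detection.  All 2k linear
#' programs are solved in one solver batch.
#'
#' @param model a `metabolic_model` (zero flux must be feasible, which holds
#'   whenever `0` lies within every reaction's bounds).
#' @param reactions subset of reaction ids (default: all).
#' @return an `fva_result`: data.frame with columns `id`, `vmin`, `vmax`.
#'   Unbounded directions are clamped to the reaction's own bounds.
#' @export
flux_variability <- function(model, reactions = NULL) {
  ids <- if (is.null(reactions)) reaction_ids(model) else reactions
  stopifnot(all(ids %in% reaction_ids(model)))
  all_ids <- reaction_ids(model)
  m <- length(all_ids)
  b <- model_bounds(model)
  if (any(b$lb > 0) || any(b$ub < 0)) {
    # zero flux infeasible a priori; report rather than guess
    stop("flux_variability: zero flux is not within bounds for ",
         paste(all_ids[b$lb > 0 | b$ub < 0], collapse = ", "),
         call. = FALSE)
  }
  probs <- list()
  for (id in ids) {
    j <- match(id, all_ids)
    obj <- numeric(m); obj[j] <- 1
    probs <- c(probs,
               list(steady_state_lp(model, obj, maximize = FALSE),
                    steady_state_lp(model, obj, maximize = TRUE)))
  }
  res <- milp_solve_batch(probs)
  vmin <- vmax <- numeric(length(ids))
  for (k in seq_along(ids)) {
    j <- match(ids[k], all_ids)
    rmin <- res[[2L * k - 1L]]
    rmax <- res[[2L * k]]
    vmin[k] <- if (rmin$success) max(rmin$objective, b$lb[j]) else b$lb[j]
    vmax[k] <- if (rmax$success) min(rmax$objective, b$ub[j]) else b$ub[j]
    if (!rmin$success && rmin$status != 3L) {
      stop("FVA: LP failed for '", ids[k], "': ", rmin$message, call. = FALSE)
    }
    if (!rmax$success && rmax$status != 3L) {
      stop("FVA: LP failed for '", ids[k], "': ", rmax$message, call. = FALSE)
    }
  }
  structure(data.frame(id = ids, vmin = vmin, vmax = vmax,
                       stringsAsFactors = FALSE),
            class = c("fva_result", "data.frame"))
}

#' Blocked reactions according to an FVA result
#' @param fva an `fva_result`.
#' @param tol activity tolerance on LP optima (default 1e-9).
#' @return character vector of reaction ids with `max(|vmin|, |vmax|) < tol`.
#' @export
blocked_reactions <- function(fva, tol = 1e-9) {
  fva$id[pmax(abs(fva$vmin), abs(fva$vmax)) < tol]
}

#' Remove dead-end (blocked) reactions
#'
#' Iterates FVA and deletion of blocked reactions to a fixed point, then
#' drops metabolites no longer associated with any reaction.  The result is
#' flux-consistent: every remaining reaction can carry `|v| >= tol` in some
#' feasible steady-state flux distribution.
#'
#' @param model a `metabolic_model`, normally after [open_exchanges()].
#' @param tol blocked-reaction tolerance on LP optima (default 1e-9, the
#'   solver noise floor).
#' @return the trimmed model, with an attribute `removed` listing the
#'   deleted reaction ids in removal order.
#' @export
trim_dead_ends <- function(model, tol = 1e-9) {
  removed <- character()
  repeat {
    fva <- flux_variability(model)
    dead <- blocked_reactions(fva, tol = tol)
    if (length(dead) == 0L) break
    if (length(dead) == length(model$reactions)) {
      stop("trim_dead_ends: every reaction is blocked; degenerate input",
           call. = FALSE)
    }
    removed <- c(removed, dead)
    model <- drop_reactions(model, dead, drop_orphans = TRUE)
  }
  attr(model, "removed") <- removed
  model
}
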