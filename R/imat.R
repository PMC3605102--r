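# The agreement-score MILP (iMAT): find a steady-state flux distribution
# maximizing the number of highly expressed reactions carrying flux at least
# eps (in either direction) plus the number of lowly expressed reactions
# carrying exactly none, with the biomass reaction forced active.
#
#   max  sum_{i in rH} (y+_i + y-_i) + sum_{i in rL} y_i
#   s.t. S v = 0,  lb <= v <= ub,
#        y+_i = 1  =>  v_i >= +eps        (i in rH)
#        y-_i = 1  =>  v_i <= -eps        (i in rH, reversible)
#        y_i  = 1  =>  v_i  = 0           (i in rL)
#        v_biomass >= biomass_min
#
# Indicators are linearized with the model's own finite bounds as big-M, so
# the model must have finite bounds (guaranteed after open_exchanges()).

#' Define an iMAT agreement-score problem
#'
#' @param model an opened, trimmed `metabolic_model` with finite bounds.
#' @param calls a `reaction_calls` object (from [call_reactions()] or
#'   [reaction_calls()]).
#' @param eps activation threshold: an rH reaction counts as agreeing when
#'   `|v| >= eps` (default 1.0).
#' @param biomass id of the biomass reaction (default: the flagged one).
#' @param biomass_min minimum biomass flux quantifying "non-zero biomass";
#'   defaults to `eps` so that a single activation scale is used.
#' @return an `imat_problem`.
#' @export
imat_problem <- function(model, calls, eps = 1, biomass = biomass_id(model),
                         biomass_min = eps) {
  stopifnot(inherits(model, "metabolic_model"), eps > 0)
  if (!inherits(calls, "reaction_calls")) {
    stop("`calls` must be a reaction_calls object", call. = FALSE)
  }
  if (is.null(biomass) || !biomass %in% reaction_ids(model)) {
    stop("imat_problem: no biomass reaction designated in the model",
         call. = FALSE)
  }
  unknown <- setdiff(c(calls$rH, calls$rL), reaction_ids(model))
  if (length(unknown) > 0L) {
    stop("reaction calls reference reactions absent from the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  b <- model_bounds(model)
  inf_b <- b$id[is.infinite(b$lb) | is.infinite(b$ub)]
  if (length(inf_b) > 0L) {
    stop("imat_problem: infinite bounds on ",
         paste(inf_b, collapse = ", "),
         "; run open_exchanges() first so big-M constants are finite",
         call. = FALSE)
  }
  structure(list(model = model, rH = calls$rH, rL = calls$rL, eps = eps,
                 biomass = biomass, biomass_min = biomass_min),
            class = "imat_problem")
}

#' @export
print.imat_problem <- function(x, ...) {
  cat("<imat_problem> ", length(x$model$reactions), " reactions; |rH| = ",
      length(x$rH), ", |rL| = ", length(x$rL), "; eps = ", x$eps,
      "; biomass '", x$biomass, "' >= ", x$biomass_min, "\n", sep = "")
  invisible(x)
}

# Build the MILP for an imat_problem; `override` is a named list
# reaction id -> c(lb, ub) used by the alternative-optima exploration.
# Returns list(problem=milp_problem, layout) where layout maps variables.
imat_milp <- function(p, override = NULL) {
  model <- p$model
  ids <- reaction_ids(model)
  m <- length(ids)
  b <- model_bounds(model)
  lb <- b$lb; ub <- b$ub
  if (!is.null(override)) {
    for (id in names(override)) {
      j <- match(id, ids)
      lb[j] <- override[[id]][1L]
      ub[j] <- override[[id]][2L]
    }
  }
  jb <- match(p$biomass, ids)
  lb[jb] <- max(lb[jb], p$biomass_min)
  if (any(lb > ub)) return(NULL)            # trivially infeasible modulation
  iH <- match(p$rH, ids)
  revH <- iH[lb[iH] <= -p$eps]              # reverse indicator only useful here
  iL <- match(p$rL, ids)
  nv <- m
  idx_yp <- if (length(iH) > 0L) nv + seq_along(iH) else integer()
  nv <- nv + length(iH)
  idx_ym <- if (length(revH) > 0L) nv + seq_along(revH) else integer()
  nv <- nv + length(revH)
  idx_y <- if (length(iL) > 0L) nv + seq_along(iL) else integer()
  nv <- nv + length(iL)

  S <- stoichiometric_matrix(model)
  rows <- list(); rlb <- numeric(); rub <- numeric()
  add_row <- function(row, lo, hi) {
    rows[[length(rows) + 1L]] <<- row
    rlb[length(rlb) + 1L] <<- lo
    rub[length(rub) + 1L] <<- hi
  }
  for (i in seq_len(nrow(S))) {
    row <- numeric(nv); row[seq_len(m)] <- S[i, ]
    add_row(row, 0, 0)
  }
  for (k in seq_along(iH)) {
    j <- iH[k]
    # y+ = 1 => v_j >= eps :  v_j + (lb_j - eps) y+ >= lb_j
    row <- numeric(nv); row[j] <- 1; row[idx_yp[k]] <- lb[j] - p$eps
    add_row(row, lb[j], Inf)
  }
  for (k in seq_along(revH)) {
    j <- revH[k]
    # y- = 1 => v_j <= -eps :  v_j + (ub_j + eps) y- <= ub_j
    row <- numeric(nv); row[j] <- 1; row[idx_ym[k]] <- ub[j] + p$eps
    add_row(row, -Inf, ub[j])
    # at most one direction per rH reaction
    row <- numeric(nv)
    row[idx_yp[match(j, iH)]] <- 1; row[idx_ym[k]] <- 1
    add_row(row, -Inf, 1)
  }
  for (k in seq_along(iL)) {
    j <- iL[k]
    # y = 1 => v_j = 0 :  lb_j (1 - y) <= v_j <= ub_j (1 - y)
    row <- numeric(nv); row[j] <- 1; row[idx_y[k]] <- lb[j]
    add_row(row, lb[j], Inf)
    row <- numeric(nv); row[j] <- 1; row[idx_y[k]] <- ub[j]
    add_row(row, -Inf, ub[j])
  }
  obj <- numeric(nv)
  obj[c(idx_yp, idx_ym, idx_y)] <- 1
  vlb <- c(lb, rep(0, nv - m))
  vub <- c(ub, rep(1, nv - m))
  integrality <- c(integer(m), rep(1L, nv - m))
  list(problem = milp_problem(obj, A = do.call(rbind, rows),
                              con_lb = rlb, con_ub = rub,
                              lb = vlb, ub = vub,
                              integrality = integrality, maximize = TRUE),
       m = m, ids = ids, idx_yp = idx_yp, idx_ym = idx_ym, idx_y = idx_y,
       iH = iH, revH = revH, iL = iL)
}

imat_solution_from_result <- function(p, layout, res,
                                      modulation = "none",
                                      target = NA_character_) {
  ids <- layout$ids
  v <- stats::setNames(res$x[seq_len(layout$m)], ids)
  yplus <- stats::setNames(round(res$x[layout$idx_yp]), ids[layout$iH])
  yminus <- stats::setNames(round(res$x[layout$idx_ym]), ids[layout$revH])
  y <- stats::setNames(round(res$x[layout$idx_y]), ids[layout$iL])
  structure(list(flux = v, score = as.integer(round(res$objective)),
                 yplus = yplus, yminus = yminus, y = y,
                 eps = p$eps, modulation = modulation, target = target),
            class = "imat_solution")
}

#' Solve the iMAT agreement-score MILP
#'
#' @param problem an [imat_problem()].
#' @return an `imat_solution`: list with `flux` (named vector), integer
#'   `score`, and the indicator vectors `yplus`, `yminus` (rH) and `y` (rL).
#'   The score is provably maximal (zero MIP gap).
#' @export
solve_imat <- function(problem) {
  stopifnot(inherits(problem, "imat_problem"))
  built <- imat_milp(problem)
  if (is.null(built)) {
    stop("iMAT infeasible: biomass minimum conflicts with reaction bounds",
         call. = FALSE)
  }
  res <- milp_solve(built$problem)
  if (!res$success) {
    stop("iMAT MILP infeasible or failed (status ", res$status, "): ",
         res$message, "; binding constraints include S v = 0 and v_",
         problem$biomass, " >= ", problem$biomass_min, call. = FALSE)
  }
  imat_solution_from_result(problem, built, res)
}

#' @export
print.imat_solution <- function(x, ...) {
  nact <- sum(abs(x$flux) > 1e-6)
  cat("<imat_solution> agreement score ", x$score, "; ", nact, "/",
      length(x$flux), " reactions active\n", sep = "")
  invisible(x)
}

#' Active reactions of a flux vector
#' @param flux named numeric vector.
#' @param activity_tol numeric activity threshold (default 1e-6).
#' @return character vector of ids with `|v| > activity_tol`.
#' @export
active_reactions <- function(flux, activity_tol = 1e-6) {
  names(flux)[abs(flux) > activity_tol]
}

#' Recompute the agreement score of a flux vector
#'
#' Counts rH reactions with `|v| >= eps` plus rL reactions with
#' `|v| <= zero_tol`; used to verify solver-reported scores independently of
#' the indicator variables.
#' @param problem an `imat_problem`.
#' @param flux named flux vector over the problem's reactions.
#' @param zero_tol numeric tolerance for "carries no flux" (default 1e-6).
#' @export
agreement_score <- function(problem, flux, zero_tol = 1e-6) {
  vH <- abs(flux[problem$rH])
  vL <- abs(flux[problem$rL])
  # eps comparison is slack by the same numerical tolerance
  sum(vH >= problem$eps - zero_tol) + sum(vL <= zero_tol)
}
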