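# Metabolic-state prediction: minimize the total flux through the network
# subject to every high-frequency reaction and the biomass reaction being
# active, with each reversible reaction split into forward and reverse
# half-reactions:
#
#   min  sum_j (v+_j + v-_j)
#   s.t. S (v+ - v-) = 0,  0 <= v+_j <= max(ub_j, 0),
#                          0 <= v-_j <= max(-lb_j, 0)
#        for each forced reaction j:  y_j = 1 => v+_j in [eps, ub_j]
#                                     y_j = 0 => v-_j in [eps, -lb_j]
#        (irreversible forced reactions simply get v+_j >= eps)
#
# plus FBA gene-deletion essentiality and the sensitivity/PPV scoring used
# to validate predictions.

#' Minimize total flux with forced core activity
#'
#' @param model a `metabolic_model` with finite bounds (context model).
#' @param hfr reaction ids forced to be active (the high-frequency set);
#'   the biomass reaction is always added.
#' @param eps minimum activation flux for forced reactions (default 1.0).
#' @param biomass id of the biomass reaction (default: the flagged one).
#' @return a `flux_state`: list with `flux` (named net flux vector),
#'   `total_flux` (the minimized sum of split fluxes), and `direction`
#'   (named +1/-1 per forced reaction).
#' @export
minimize_total_flux <- function(model, hfr, eps = 1,
                                biomass = biomass_id(model)) {
  stopifnot(inherits(model, "metabolic_model"), eps > 0)
  if (is.null(biomass)) {
    stop("minimize_total_flux: no biomass reaction designated", call. = FALSE)
  }
  hfr <- union(as.character(hfr), biomass)
  stopifnot(all(hfr %in% reaction_ids(model)))
  built <- minflux_milp(model, hfr, eps)
  res <- milp_solve(built$problem)
  if (!res$success) {
    first_fail <- minflux_first_failure(model, hfr, eps)
    stop("minimize_total_flux: joint activation of the forced set is ",
         "infeasible (status ", res$status, ")",
         if (!is.na(first_fail)) paste0(
           "; first failing incremental activation: '", first_fail, "'"),
         call. = FALSE)
  }
  minflux_state_from_result(built, res)
}

minflux_milp <- function(model, forced, eps) {
  ids <- reaction_ids(model)
  m <- length(ids)
  b <- model_bounds(model)
  if (any(is.infinite(b$lb)) || any(is.infinite(b$ub))) {
    stop("minimize_total_flux: model must have finite bounds", call. = FALSE)
  }
  ubp <- pmax(b$ub, 0)            # forward capacity
  ubm <- pmax(-b$lb, 0)           # reverse capacity
  idx_f <- match(forced, ids)
  rev_forced <- idx_f[b$lb[idx_f] < 0]      # need a direction selector
  irr_forced <- setdiff(idx_f, rev_forced)
  nv <- 2L * m + length(rev_forced)
  idx_y <- if (length(rev_forced) > 0L) 2L * m + seq_along(rev_forced)
           else integer()

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
  vlb <- c(rep(0, 2L * m), rep(0, length(rev_forced)))
  vub <- c(ubp, ubm, rep(1, length(rev_forced)))
  for (j in irr_forced) {
    vlb[j] <- eps                       # v+ >= eps outright
  }
  for (k in seq_along(rev_forced)) {
    j <- rev_forced[k]
    # y = 1: v+ in [eps, ub], v- = 0;  y = 0: v- in [eps, -lb], v+ = 0
    row <- numeric(nv); row[j] <- 1; row[idx_y[k]] <- -eps
    add_row(row, 0, Inf)                # v+ >= eps y
    row <- numeric(nv); row[j] <- 1; row[idx_y[k]] <- -ubp[j]
    add_row(row, -Inf, 0)               # v+ <= ub y
    row <- numeric(nv); row[m + j] <- 1; row[idx_y[k]] <- eps
    add_row(row, eps, Inf)              # v- + eps y >= eps  (v- >= eps(1-y))
    row <- numeric(nv); row[m + j] <- 1; row[idx_y[k]] <- ubm[j]
    add_row(row, -Inf, ubm[j])          # v- <= ubm (1 - y)
  }
  obj <- c(rep(1, 2L * m), rep(0, length(rev_forced)))
  integrality <- c(integer(2L * m), rep(1L, length(rev_forced)))
  list(problem = milp_problem(obj, A = do.call(rbind, rows),
                              con_lb = rlb, con_ub = rub,
                              lb = vlb, ub = vub,
                              integrality = integrality, maximize = FALSE),
       ids = ids, m = m, forced = forced, rev_forced = rev_forced,
       idx_y = idx_y)
}

minflux_state_from_result <- function(built, res) {
  m <- built$m
  vplus <- res$x[seq_len(m)]
  vminus <- res$x[m + seq_len(m)]
  overlap <- pmin(vplus, vminus)
  if (any(overlap > 1e-6)) {
    # cannot happen at a true optimum (both directions add to the objective)
    warning("simultaneously active forward and reverse fluxes detected; ",
            "reporting net fluxes")
  }
  flux <- stats::setNames(vplus - vminus, built$ids)
  direction <- stats::setNames(ifelse(flux[built$forced] >= 0, 1L, -1L),
                               built$forced)
  structure(list(flux = flux, total_flux = sum(vplus) + sum(vminus),
                 direction = direction, forced = built$forced),
            class = "flux_state")
}

# find the first reaction whose incremental activation makes the joint
# problem infeasible (error-path diagnostic)
minflux_first_failure <- function(model, forced, eps) {
  for (k in seq_along(forced)) {
    built <- minflux_milp(model, forced[seq_len(k)], eps)
    if (!milp_solve(built$problem)$success) return(forced[k])
  }
  NA_character_
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> total flux ", format(x$total_flux), "; ",
      sum(abs(x$flux) > 1e-6), "/", length(x$flux),
      " reactions active; ", length(x$forced), " forced\n", sep = "")
  invisible(x)
}

#' Maximal biomass flux by FBA
#'
#' Maximizes the biomass flux over `{S v = 0, lb <= v <= ub}`.
#' @param model a `metabolic_model` with a designated biomass reaction.
#' @return the LP maximum (0 with attribute `infeasible = TRUE` if the LP
#'   is infeasible); the flux vector attained is attached as attribute
#'   `flux`.
#' @export
fba_max_biomass <- function(model) {
  bio <- biomass_id(model)
  if (is.null(bio)) stop("fba_max_biomass: no biomass reaction", call. = FALSE)
  ids <- reaction_ids(model)
  obj <- as.numeric(ids == bio)
  res <- milp_solve(steady_state_lp(model, obj, maximize = TRUE))
  if (!res$success) {
    if (res$status == 3L) {               # unbounded: clamp to own bound
      return(model$reactions[[bio]]$ub)
    }
    return(structure(0, infeasible = TRUE))
  }
  structure(res$objective, flux = stats::setNames(res$x, ids))
}

# close every reaction whose GPR evaluates FALSE when `genes` are deleted
knockout_model <- function(model, genes) {
  values <- stats::setNames(rep(0, length(genes)), genes)
  closed <- character()
  for (id in reaction_ids(model)) {
    r <- model$reactions[[id]]
    if (is.null(r$gpr$root)) next
    if (eval_gpr(r$gpr, values, missing = 1) == 0) closed <- c(closed, id)
  }
  if (length(closed) > 0L) model <- set_bounds(model, closed, lb = 0, ub = 0)
  structure(model, closed = closed)
}

#' Single-gene deletion by FBA
#'
#' Evaluates every GPR with the gene set to FALSE (two-valued logic, all
#' other genes TRUE); reactions whose rule evaluates FALSE get bounds
#' `[0, 0]`, and the gene is essential if the maximal biomass flux of the
#' perturbed model falls below `growth_tol`.
#'
#' @param model a `metabolic_model`.
#' @param gene a gene id present in the model.
#' @param growth_tol growth threshold (default 1e-6).
#' @return list with `growth` (FBA maximum) and `essential` (logical).
#' @export
single_gene_deletion <- function(model, gene, growth_tol = 1e-6) {
  if (!gene %in% model$genes) {
    stop("single_gene_deletion: gene '", gene, "' not in the model",
         call. = FALSE)
  }
  growth <- as.numeric(fba_max_biomass(knockout_model(model, gene)))
  list(growth = growth, essential = growth < growth_tol)
}

#' FBA essentiality screen over all model genes
#'
#' Runs [single_gene_deletion()] for every gene, with all deletion LPs
#' solved in one solver batch.
#'
#' @param model a `metabolic_model` with a biomass reaction.
#' @param genes genes to screen (default: all model genes).
#' @param growth_tol growth threshold (default 1e-6).
#' @return data.frame with columns `gene`, `growth`, `essential`.
#' @export
predict_essential_genes <- function(model, genes = model$genes,
                                    growth_tol = 1e-6) {
  stopifnot(all(genes %in% model$genes))
  bio <- biomass_id(model)
  if (is.null(bio)) stop("predict_essential_genes: no biomass reaction",
                         call. = FALSE)
  ids <- reaction_ids(model)
  obj <- as.numeric(ids == bio)
  probs <- lapply(genes, function(g) {
    steady_state_lp(knockout_model(model, g), obj, maximize = TRUE)
  })
  res <- milp_solve_batch(probs)
  growth <- vapply(seq_along(genes), function(k) {
    r <- res[[k]]
    if (r$success) r$objective
    else if (r$status == 3L) model$reactions[[bio]]$ub
    else 0
  }, numeric(1L))
  data.frame(gene = as.character(genes), growth = growth,
             essential = growth < growth_tol,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sensitivity and positive predictive value of essentiality predictions
#'
#' Genes in `excluded` (e.g. genes essential on the reference medium, whose
#' deletion mutants were never assayed on the test medium) are removed from
#' both the predicted and observed sets before counting.  True positives are
#' correctly predicted essential genes; sensitivity = tp / (tp + fn),
#' PPV = tp / (tp + fp).
#'
#' @param predicted character vector of genes predicted essential.
#' @param observed character vector of genes observed essential.
#' @param universe all genes assessed (predictions and observations must be
#'   subsets).
#' @param excluded genes excluded from scoring.
#' @return an `essentiality_report`: list with counts `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `ppv` (NA when undefined), `excluded`, and a
#'   per-gene `table` with class in {tp, fp, fn, tn, excluded}.
#' @export
essentiality_metrics <- function(predicted, observed, universe,
                                 excluded = character()) {
  predicted <- as.character(predicted); observed <- as.character(observed)
  universe <- as.character(universe); excluded <- as.character(excluded)
  stopifnot(all(predicted %in% universe), all(observed %in% universe))
  scored <- setdiff(universe, excluded)
  p <- intersect(predicted, scored)
  o <- intersect(observed, scored)
  tp <- length(intersect(p, o))
  fp <- length(setdiff(p, o))
  fn <- length(setdiff(o, p))
  tn <- length(scored) - tp - fp - fn
  cls <- ifelse(universe %in% excluded, "excluded",
         ifelse(universe %in% p & universe %in% o, "tp",
         ifelse(universe %in% p, "fp",
         ifelse(universe %in% o, "fn", "tn"))))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
                 ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
                 excluded = excluded,
                 table = data.frame(gene = universe,
                                    predicted = universe %in% p,
                                    observed = universe %in% o,
                                    class = cls, stringsAsFactors = FALSE)),
            class = "essentiality_report")
}

#' @export
print.essentiality_report <- function(x, ...) {
  cat("<essentiality_report> tp = ", x$tp, ", fp = ", x$fp, ", fn = ", x$fn,
      ", tn = ", x$tn, "\n  sensitivity = ",
      if (is.na(x$sensitivity)) "undefined" else
        sprintf("%.1f%%", 100 * x$sensitivity),
      ", PPV = ",
      if (is.na(x$ppv)) "undefined" else sprintf("%.1f%%", 100 * x$ppv),
      if (length(x$excluded) > 0L)
        paste0("  (", length(x$excluded), " genes excluded)") else "",
      "\n", sep = "")
  invisible(x)
}
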