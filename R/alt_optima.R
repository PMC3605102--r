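# Exploration of alternative optimal iMAT solutions.  Every reaction is
# forced, in turn, to be inactive, to carry a positive flux (>= eps), and --
# if reversible -- to carry a negative flux (<= -eps); each modified MILP is
# solved to proven optimality and solutions attaining the global maximum
# agreement score are retained.  Counting how often each reaction is active
# across the retained solutions yields the high-frequency (always active)
# and zero-frequency (never active) reaction sets.

#' Explore alternative optimal solutions by reaction modulation
#'
#' @param problem an [imat_problem()].
#' @param activity_tol flux magnitude above which a reaction counts as
#'   active when tallying frequencies (default 1e-6: above LP noise, far
#'   below `eps`).
#' @return an `optima_ensemble`: list with
#'   \describe{
#'     \item{solutions}{retained `imat_solution`s (baseline first), all
#'       attaining the maximal score}
#'     \item{score}{the global optimum}
#'     \item{flux}{m x k matrix of retained flux vectors}
#'     \item{provenance}{data.frame of every modulation run and its outcome
#'       (`retained`, `suboptimal`, or `infeasible`)}
#'     \item{activity_count}{per-reaction count of retained solutions with
#'       `|v| > activity_tol`}
#'     \item{distinct_count}{number of distinct flux distributions after
#'       componentwise deduplication at 1e-6}
#'   }
#' @export
explore_optima <- function(problem, activity_tol = 1e-6) {
  stopifnot(inherits(problem, "imat_problem"))
  base <- solve_imat(problem)            # errors if the baseline is infeasible
  s_star <- base$score
  model <- problem$model
  ids <- reaction_ids(model)
  b <- model_bounds(model)

  mods <- list(list(target = NA_character_, modulation = "none",
                    override = NULL))
  for (j in seq_along(ids)) {
    mods <- c(mods, list(list(target = ids[j], modulation = "off",
                              override = stats::setNames(list(c(0, 0)),
                                                         ids[j]))))
    mods <- c(mods, list(list(target = ids[j], modulation = "forward",
                              override = stats::setNames(
                                list(c(problem$eps, b$ub[j])), ids[j]))))
    if (b$lb[j] < 0) {
      mods <- c(mods, list(list(target = ids[j], modulation = "reverse",
                                override = stats::setNames(
                                  list(c(b$lb[j], -problem$eps)), ids[j]))))
    }
  }
  built <- lapply(mods, function(mod) imat_milp(problem, mod$override))
  solvable <- !vapply(built, is.null, logical(1L))
  res <- vector("list", length(mods))
  res[solvable] <- milp_solve_batch(
    lapply(built[solvable], function(bb) bb$problem))

  solutions <- list()
  prov <- data.frame(target = character(), modulation = character(),
                     outcome = character(), score = integer(),
                     stringsAsFactors = FALSE)
  for (k in seq_along(mods)) {
    mod <- mods[[k]]
    if (!solvable[k] || !res[[k]]$success) {
      outcome <- "infeasible"; score <- NA_integer_
    } else {
      score <- as.integer(round(res[[k]]$objective))
      if (score == s_star) {
        outcome <- "retained"
        solutions <- c(solutions, list(imat_solution_from_result(
          problem, built[[k]], res[[k]],
          modulation = mod$modulation, target = mod$target)))
      } else {
        outcome <- "suboptimal"
      }
    }
    prov <- rbind(prov, data.frame(target = mod$target,
                                   modulation = mod$modulation,
                                   outcome = outcome, score = score,
                                   stringsAsFactors = FALSE))
  }
  flux <- vapply(solutions, function(s) s$flux, numeric(length(ids)))
  flux <- matrix(flux, nrow = length(ids),
                 dimnames = list(ids, NULL))
  structure(list(solutions = solutions, score = s_star, flux = flux,
                 provenance = prov,
                 activity_tol = activity_tol,
                 activity_count = rowSums(abs(flux) > activity_tol),
                 distinct_count = count_distinct_columns(flux, 1e-6),
                 problem = problem),
            class = "optima_ensemble")
}

count_distinct_columns <- function(mat, tol) {
  k <- ncol(mat)
  if (k <= 1L) return(k)
  keep <- rep(TRUE, k)
  for (i in seq_len(k - 1L)) {
    if (!keep[i]) next
    for (j in seq((i + 1L), k)) {
      if (keep[j] && max(abs(mat[, i] - mat[, j])) <= tol) keep[j] <- FALSE
    }
  }
  sum(keep)
}

#' @export
print.optima_ensemble <- function(x, ...) {
  cat("<optima_ensemble> score ", x$score, "; ", length(x$solutions),
      " retained solutions (", x$distinct_count, " distinct); ",
      sum(x$provenance$outcome == "suboptimal"), " suboptimal, ",
      sum(x$provenance$outcome == "infeasible"),
      " infeasible modulations\n", sep = "")
  invisible(x)
}

#' Classify reactions into high- and zero-frequency sets
#'
#' High-frequency reactions (HFR) are active in every retained optimal
#' solution; zero-frequency reactions (ZFR) are active in none.  Frequencies
#' are counted over retained raw solutions (deduplication does not affect
#' all-or-none membership).
#'
#' @param ensemble an `optima_ensemble` from [explore_optima()].
#' @param activity_tol activity threshold (default: the ensemble's).
#' @return a `frequency_sets` object: list with `HFR`, `ZFR`,
#'   `n_solutions`, and `table` (reaction, count, n_solutions, frequency,
#'   class) including intermediate-frequency reactions.
#' @export
classify_frequencies <- function(ensemble, activity_tol = NULL) {
  stopifnot(inherits(ensemble, "optima_ensemble"))
  if (length(ensemble$solutions) == 0L) {
    stop("classify_frequencies: empty ensemble", call. = FALSE)
  }
  tol <- if (is.null(activity_tol)) ensemble$activity_tol else activity_tol
  count <- rowSums(abs(ensemble$flux) > tol)
  n <- ncol(ensemble$flux)
  cls <- ifelse(count == n, "HFR", ifelse(count == 0L, "ZFR", "intermediate"))
  tab <- data.frame(reaction = rownames(ensemble$flux),
                    count = as.integer(count), n_solutions = n,
                    frequency = count / n, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(HFR = tab$reaction[tab$class == "HFR"],
                 ZFR = tab$reaction[tab$class == "ZFR"],
                 n_solutions = n, table = tab),
            class = "frequency_sets")
}

#' Construct frequency sets directly (e.g. from a frequency table file)
#' @param HFR,ZFR disjoint character vectors of reaction ids.
#' @export
frequency_sets <- function(HFR, ZFR) {
  HFR <- as.character(HFR); ZFR <- as.character(ZFR)
  if (length(intersect(HFR, ZFR)) > 0L) {
    stop("HFR and ZFR must be disjoint", call. = FALSE)
  }
  structure(list(HFR = HFR, ZFR = ZFR, n_solutions = NA_integer_,
                 table = data.frame(
                   reaction = c(HFR, ZFR),
                   count = NA_integer_, n_solutions = NA_integer_,
                   frequency = c(rep(1, length(HFR)), rep(0, length(ZFR))),
                   class = c(rep("HFR", length(HFR)),
                             rep("ZFR", length(ZFR))),
                   stringsAsFactors = FALSE)),
            class = "frequency_sets")
}

#' @export
print.frequency_sets <- function(x, ...) {
  cat("<frequency_sets> |HFR| = ", length(x$HFR), ", |ZFR| = ",
      length(x$ZFR), sep = "")
  if (!is.na(x$n_solutions)) {
    cat(" over ", x$n_solutions, " optimal solutions", sep = "")
  }
  cat("\n")
  invisible(x)
}
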