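# Discretizing gene expression into ternary calls and mapping them onto
# reactions through the Boolean gene-to-reaction rules with three-valued
# min/max logic.

#' Discretize gene expression into ternary calls
#'
#' Ranks genes by expression value and classifies the top `hi_frac` fraction
#' as highly expressed (+1), the bottom `lo_frac` fraction as lowly
#' expressed (-1) and the remainder as neither (0).  With the default 15%
#' thresholds and approximately log-normal expression values, the cutoffs
#' fall about one standard deviation above and below the mean on the log
#' scale.
#'
#' Set sizes use the ceiling rule: `ceiling(hi_frac * G)` and
#' `ceiling(lo_frac * G)` over `G` measured genes.  Ties are broken by value
#' and then by gene id, so calls are deterministic; for very small `G` the
#' low set is truncated so that no gene is called both high and low.
#'
#' @param values named numeric vector: one expression value per gene.
#' @param hi_frac,lo_frac fractions in (0, 0.5); default 0.15 each.
#' @return an `expression_calls` object: list with `calls` (named integer
#'   vector in {-1, 0, +1}), `hi_frac`, `lo_frac`.
#' @export
call_genes <- function(values, hi_frac = 0.15, lo_frac = 0.15) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            !is.null(names(values)), all(nzchar(names(values))),
            hi_frac > 0, hi_frac < 0.5, lo_frac > 0, lo_frac < 0.5)
  if (anyDuplicated(names(values))) {
    stop("call_genes: duplicated gene ids; supply one value per gene",
         call. = FALSE)
  }
  g <- length(values)
  calls <- stats::setNames(integer(g), names(values))
  if (length(unique(values)) == 1L) {
    warning("all expression values identical; no meaningful ranking, ",
            "all calls set to 0")
    return(new_expression_calls(calls, hi_frac, lo_frac))
  }
  n_hi <- ceiling(hi_frac * g)
  n_lo <- min(ceiling(lo_frac * g), g - n_hi)
  ord_desc <- order(-values, names(values))
  ord_asc <- order(values, names(values))
  calls[ord_desc[seq_len(n_hi)]] <- 1L
  calls[ord_asc[seq_len(n_lo)]] <- -1L
  new_expression_calls(calls, hi_frac, lo_frac)
}

new_expression_calls <- function(calls, hi_frac, lo_frac) {
  structure(list(calls = calls, hi_frac = hi_frac, lo_frac = lo_frac),
            class = "expression_calls")
}

#' Treat a ready-made ternary call vector as expression calls
#'
#' For pre-discretized inputs (e.g. a published gene-call table) where the
#' original continuous values are unavailable.
#' @param calls named vector with values in {-1, 0, 1}.
#' @param hi_frac,lo_frac the fractions used to produce the calls, if known.
#' @export
as_expression_calls <- function(calls, hi_frac = NA_real_,
                                lo_frac = NA_real_) {
  if (inherits(calls, "expression_calls")) return(calls)
  stopifnot(!is.null(names(calls)), all(calls %in% c(-1, 0, 1)))
  new_expression_calls(stats::setNames(as.integer(calls), names(calls)),
                       hi_frac, lo_frac)
}

#' @export
print.expression_calls <- function(x, ...) {
  cat("<expression_calls> ", length(x$calls), " genes: ",
      sum(x$calls == 1L), " high, ", sum(x$calls == -1L), " low, ",
      sum(x$calls == 0L), " neither", sep = "")
  if (!is.na(x$hi_frac)) {
    cat(sprintf("  (hi %.0f%%, lo %.0f%%)", 100 * x$hi_frac, 100 * x$lo_frac))
  }
  cat("\n")
  invisible(x)
}

#' Map gene calls onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR with three-valued logic over the order
#' -1 < 0 < +1, with AND as minimum and OR as maximum; genes without a call
#' are treated as 0.  This is the unique monotone recursive extension of the
#' flat complex/isoenzyme rules: a complex (AND) is highly expressed only if
#' all subunits are and lowly expressed if any subunit is; an isoenzyme set
#' (OR) is highly expressed if any isoform is and lowly expressed only if
#' all are.
#'
#' @param model a `metabolic_model`.
#' @param calls an `expression_calls` object or named ternary vector.
#' @return a `reaction_calls` object: list with `rH` and `rL` (disjoint
#'   character vectors of reaction ids) and `calls`, the named ternary call
#'   for every reaction with a non-empty GPR.
#' @export
call_reactions <- function(model, calls) {
  calls <- as_expression_calls(calls)
  vals <- calls$calls
  with_gpr <- names(model$reactions)[
    !vapply(model$reactions, function(r) is.null(r$gpr$root), logical(1L))]
  rcall <- vapply(with_gpr, function(id) {
    eval_gpr(model$reactions[[id]]$gpr, vals, missing = 0)
  }, numeric(1L))
  rcall <- stats::setNames(as.integer(rcall), with_gpr)
  structure(list(rH = names(rcall)[rcall == 1L],
                 rL = names(rcall)[rcall == -1L],
                 calls = rcall),
            class = "reaction_calls")
}

#' Construct reaction calls directly from rH / rL sets
#' @param rH,rL disjoint character vectors of reaction ids.
#' @export
reaction_calls <- function(rH, rL) {
  rH <- as.character(rH); rL <- as.character(rL)
  if (length(intersect(rH, rL)) > 0L) {
    stop("rH and rL must be disjoint", call. = FALSE)
  }
  calls <- stats::setNames(c(rep(1L, length(rH)), rep(-1L, length(rL))),
                           c(rH, rL))
  structure(list(rH = rH, rL = rL, calls = calls), class = "reaction_calls")
}

#' @export
print.reaction_calls <- function(x, ...) {
  cat("<reaction_calls> rH: ", length(x$rH), " reactions; rL: ",
      length(x$rL), " reactions\n", sep = "")
  invisible(x)
}
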