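# Constraint-based metabolic model container.
#
# A metabolic_model holds an ordered metabolite table, an ordered list of
# reactions (id, name, stoichiometry as a named coefficient vector with
# negative = consumed, bounds, GPR rule, flags) and the derived gene set.
# The flux space is { v : S v = 0, lb <= v <= ub } with S the n x m
# stoichiometric matrix assembled by stoichiometric_matrix().

#' Create a reaction
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed, positive = produced); must be non-empty.
#' @param lb,ub flux bounds, `lb <= ub`.
#' @param gpr GPR rule string or `gpr_rule` (default: no gene association).
#' @param name free-text name.
#' @param is_biomass flag the designated biomass reaction.
#' @return a `reaction` object.  A reaction with exactly one stoichiometric
#'   entry is an exchange (boundary) reaction; the flag is derived, not set.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, gpr = "",
                     name = id, is_biomass = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- unlist(stoich)
  if (length(stoich) == 0L || is.null(names(stoich)) ||
      any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector",
         call. = FALSE)
  }
  if (anyDuplicated(names(stoich))) {
    stop("reaction '", id, "': duplicated metabolite in stoichiometry",
         call. = FALSE)
  }
  if (!(lb <= ub)) {
    stop("reaction '", id, "': lb > ub", call. = FALSE)
  }
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = parse_gpr(gpr),
                 is_exchange = length(stoich) == 1L,
                 is_biomass = isTRUE(is_biomass)),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction> ", x$id, ": ", format_reaction_equation(x$stoich, x$lb < 0),
      "  [", x$lb, ", ", x$ub, "]", sep = "")
  if (x$is_biomass) cat("  (biomass)")
  if (x$is_exchange) cat("  (exchange)")
  g <- format(x$gpr)
  if (nzchar(g)) cat("  gpr: ", g, sep = "")
  cat("\n")
  invisible(x)
}

#' Create a metabolic model
#'
#' @param reactions list of [reaction()] objects.
#' @param metabolites optional data.frame with columns `id`, `name`,
#'   `compartment`; defaults to the metabolites appearing in the reaction
#'   stoichiometries, in order of first appearance, with the compartment
#'   taken from a trailing `[tag]` in the id when present.
#' @param id model identifier (free text).
#' @return a `metabolic_model` with fields `metabolites` (data.frame),
#'   `reactions` (named list), `genes` (union of GPR leaves) and `id`.
#' @export
metabolic_model <- function(reactions, metabolites = NULL, id = "model") {
  stopifnot(is.list(reactions), length(reactions) > 0L)
  rids <- vapply(reactions, function(r) r$id, character(1L))
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  }
  names(reactions) <- rids
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (is.null(metabolites)) {
    metabolites <- data.frame(id = used,
                              name = sub("\\[[^][]*\\]$", "", used),
                              compartment = met_compartment(used),
                              stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
    if (anyDuplicated(metabolites$id)) {
      stop("duplicate metabolite ids", call. = FALSE)
    }
    missing <- setdiff(used, metabolites$id)
    if (length(missing) > 0L) {
      stop("stoichiometry references unknown metabolites: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (sum(vapply(reactions, function(r) r$is_biomass, logical(1L))) > 1L) {
    stop("at most one reaction may be flagged as biomass", call. = FALSE)
  }
  genes <- sort(unique(unlist(lapply(reactions, function(r) r$gpr$genes))))
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 genes = as.character(genes)),
            class = "metabolic_model")
}

met_compartment <- function(ids) {
  comp <- sub("^.*\\[([^][]*)\\]$", "\\1", ids)
  comp[comp == ids] <- ""
  comp
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, ", length(x$genes), " genes\n",
      sep = "")
  nex <- sum(vapply(x$reactions, function(r) r$is_exchange, logical(1L)))
  bio <- biomass_id(x)
  cat("  exchanges: ", nex, "; biomass: ",
      if (is.null(bio)) "<none>" else bio, "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `metabolic_model`.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Id of the designated biomass reaction (or NULL)
#' @param model a `metabolic_model`.
#' @export
biomass_id <- function(model) {
  flag <- vapply(model$reactions, function(r) r$is_biomass, logical(1L))
  if (!any(flag)) NULL else names(model$reactions)[flag][1L]
}

#' Ids of exchange (boundary) reactions
#'
#' A reaction is an exchange if and only if its stoichiometry has exactly one
#' entry, i.e. it imports or exports a single metabolite across the system
#' boundary.
#' @param model a `metabolic_model`.
#' @export
exchange_ids <- function(model) {
  flag <- vapply(model$reactions, function(r) r$is_exchange, logical(1L))
  names(model$reactions)[flag]
}

#' Flux bounds of a model
#' @param model a `metabolic_model`.
#' @return data.frame with columns `id`, `lb`, `ub` in reaction order.
#' @export
model_bounds <- function(model) {
  data.frame(id = reaction_ids(model),
             lb = vapply(model$reactions, function(r) r$lb, numeric(1L)),
             ub = vapply(model$reactions, function(r) r$ub, numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Set flux bounds on one or more reactions
#' @param model a `metabolic_model`.
#' @param ids reaction ids.
#' @param lb,ub new bounds, recycled along `ids`; `NA` leaves a bound as is.
#' @export
set_bounds <- function(model, ids, lb = NA, ub = NA) {
  stopifnot(all(ids %in% reaction_ids(model)))
  lb <- rep_len(lb, length(ids))
  ub <- rep_len(ub, length(ids))
  for (k in seq_along(ids)) {
    r <- model$reactions[[ids[k]]]
    if (!is.na(lb[k])) r$lb <- as.numeric(lb[k])
    if (!is.na(ub[k])) r$ub <- as.numeric(ub[k])
    if (r$lb > r$ub) stop("set_bounds: lb > ub for '", ids[k], "'",
                          call. = FALSE)
    model$reactions[[ids[k]]] <- r
  }
  model
}

#' Remove reactions (and optionally orphaned metabolites) from a model
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to delete.
#' @param drop_orphans drop metabolites left unused by any reaction.
#' @export
drop_reactions <- function(model, ids, drop_orphans = TRUE) {
  if (length(ids) == 0L) return(model)
  stopifnot(all(ids %in% reaction_ids(model)))
  keep <- setdiff(reaction_ids(model), ids)
  if (length(keep) == 0L) {
    stop("dropping these reactions would empty the model", call. = FALSE)
  }
  reactions <- model$reactions[keep]
  mets <- model$metabolites
  if (drop_orphans) {
    used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
    mets <- mets[mets$id %in% used, , drop = FALSE]
    rownames(mets) <- NULL
  }
  metabolic_model(reactions, metabolites = mets, id = model$id)
}

#' Assemble the stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix S of dimension n metabolites x m reactions,
#'   with `S[i, j]` the coefficient of metabolite i in reaction j;
#'   dimnames carry the ids.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- reaction_ids(model)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Genes associated with each reaction
#' @param model a `metabolic_model`.
#' @return named list mapping reaction id -> character vector of gene ids.
#' @export
reaction_genes <- function(model) {
  lapply(model$reactions, function(r) r$gpr$genes)
}
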