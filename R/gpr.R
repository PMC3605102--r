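# Gene-protein-reaction (GPR) rules.
#
# A GPR is a Boolean expression over gene identifiers in which AND encodes a
# protein complex (all subunits required) and OR encodes isoenzymes (any one
# suffices).  Rules are stored as expression trees: a leaf is a gene id
# (character scalar), an internal node is list(op = "and"|"or", args = list
# of >= 2 children).  The empty rule (no gene association) is NULL.
#
# The same min/max evaluator serves two-valued deletion logic (genes in
# {0, 1}) and the ternary expression logic (calls in {-1, 0, +1}): AND is
# the minimum and OR the maximum over the order -1 < 0 < +1.

#' Parse a Boolean gene-protein-reaction rule
#'
#' Parses rules such as `"(g1 AND g2) OR (g3 AND g4)"` into an expression
#' tree.  `AND`/`OR` keywords are case-insensitive and `AND` binds tighter
#' than `OR`; any other token is taken verbatim (case-sensitively) as a gene
#' id.  A blank string yields the empty rule (no gene association).
#'
#' @param text character scalar; the rule.
#' @return an object of class `gpr_rule` with fields `root` (the tree, or
#'   `NULL` for the empty rule) and `genes` (character vector of leaf ids).
#' @examples
#' r <- parse_gpr("(g1 AND g2) OR (g3 AND g4)")
#' gpr_genes(r)
#' eval_gpr(r, c(g1 = 1, g2 = 1, g3 = -1, g4 = 0))
#' @export
parse_gpr <- function(text) {
  if (inherits(text, "gpr_rule")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(new_gpr(NULL, ""))
  }
  toks <- gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L
  root <- gpr_parse_or(state, text)
  if (state$i <= nrow(state$toks)) {
    gpr_error(text, state$toks$pos[state$i],
              sprintf("unexpected token '%s'", state$toks$tok[state$i]))
  }
  new_gpr(root, text)
}

new_gpr <- function(root, text) {
  structure(list(root = root, genes = gpr_leaves(root)),
            class = "gpr_rule")
}

gpr_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^\\s()]+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(tok = character(), pos = integer()))
  toks <- regmatches(text, list(m))[[1L]]
  data.frame(tok = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

gpr_error <- function(text, pos, msg) {
  stop(sprintf("GPR parse error at position %d in \"%s\": %s",
               pos, text, msg), call. = FALSE)
}

gpr_peek <- function(state) {
  if (state$i > nrow(state$toks)) NA_character_ else state$toks$tok[state$i]
}

gpr_pos <- function(state, text) {
  if (state$i > nrow(state$toks)) nchar(text) + 1L else state$toks$pos[state$i]
}

gpr_is_op <- function(tok, op) !is.na(tok) && tolower(tok) == op

# expr := term (OR term)*
gpr_parse_or <- function(state, text) {
  args <- list(gpr_parse_and(state, text))
  while (gpr_is_op(gpr_peek(state), "or")) {
    state$i <- state$i + 1L
    args <- c(args, list(gpr_parse_and(state, text)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

# term := factor (AND factor)*
gpr_parse_and <- function(state, text) {
  args <- list(gpr_parse_factor(state, text))
  while (gpr_is_op(gpr_peek(state), "and")) {
    state$i <- state$i + 1L
    args <- c(args, list(gpr_parse_factor(state, text)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

# factor := '(' expr ')' | gene
gpr_parse_factor <- function(state, text) {
  tok <- gpr_peek(state)
  pos <- gpr_pos(state, text)
  if (is.na(tok)) gpr_error(text, pos, "dangling operator: expected a gene or '('")
  if (tok == "(") {
    state$i <- state$i + 1L
    inner <- gpr_parse_or(state, text)
    if (!identical(gpr_peek(state), ")")) {
      gpr_error(text, gpr_pos(state, text), "unbalanced parentheses: expected ')'")
    }
    state$i <- state$i + 1L
    return(inner)
  }
  if (tok == ")") gpr_error(text, pos, "unbalanced parentheses: unexpected ')'")
  if (gpr_is_op(tok, "and") || gpr_is_op(tok, "or")) {
    gpr_error(text, pos, sprintf("dangling operator '%s'", tok))
  }
  state$i <- state$i + 1L
  tok
}

gpr_leaves <- function(node) {
  if (is.null(node)) return(character())
  if (is.character(node)) return(node)
  unique(unlist(lapply(node$args, gpr_leaves)))
}

#' Genes referenced by a GPR rule
#' @param rule a `gpr_rule` (or rule string).
#' @return character vector of gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) parse_gpr(rule)$genes

#' Evaluate a GPR rule with min/max logic
#'
#' Evaluates the rule with AND mapped to the minimum and OR to the maximum of
#' its arguments.  With gene values in `{-1, 0, +1}` this is the ternary
#' expression logic (a complex is highly expressed only if all subunits are,
#' lowly expressed if any subunit is; isoenzymes the other way around); with
#' values in `{0, 1}` it is ordinary Boolean logic, as used for gene
#' deletions.
#'
#' @param rule a `gpr_rule` (or rule string).
#' @param values named numeric vector of per-gene values.
#' @param missing value used for genes absent from `values` (default 0).
#' @param empty value returned for the empty rule (default `NA`).
#' @return numeric scalar.
#' @export
eval_gpr <- function(rule, values, missing = 0, empty = NA_real_) {
  rule <- parse_gpr(rule)
  if (is.null(rule$root)) return(empty)
  eval_node <- function(node) {
    if (is.character(node)) {
      if (node %in% names(values)) return(as.numeric(values[[node]]))
      return(as.numeric(missing))
    }
    vals <- vapply(node$args, eval_node, numeric(1L))
    if (node$op == "and") min(vals) else max(vals)
  }
  eval_node(rule$root)
}

#' Serialize a GPR rule back to a Boolean string
#'
#' The output round-trips: `parse_gpr(format(rule))` is logically equivalent
#' to `rule`.  Parentheses are emitted only where OR appears under AND.
#'
#' @param x a `gpr_rule`.
#' @param ... ignored.
#' @return character scalar (empty string for the empty rule).
#' @export
format.gpr_rule <- function(x, ...) {
  fmt <- function(node, parent_and) {
    if (is.character(node)) return(node)
    sep <- if (node$op == "and") " and " else " or "
    inner <- vapply(node$args, fmt, character(1L),
                    parent_and = node$op == "and")
    s <- paste(inner, collapse = sep)
    if (node$op == "or" && parent_and) paste0("(", s, ")") else s
  }
  if (is.null(x$root)) "" else fmt(x$root, FALSE)
}

#' @export
print.gpr_rule <- function(x, ...) {
  if (is.null(x$root)) {
    cat("<gpr_rule: empty (no gene association)>\n")
  } else {
    cat("<gpr_rule> ", format(x), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.character.gpr_rule <- function(x, ...) format(x)
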