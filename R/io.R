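# Reading and writing the plain-text interchange formats: the reaction-list
# CSV dialect (one reaction per row with an equation string such as
# "2 A[c] + B[c] -> C[e]"), gene/reaction call TSVs, frequency tables and
# flux-state tables.  All files are ordinary CSV/TSV handled with base R.

ARROW_IRREV <- "->"
ARROW_REV <- "<=>"

#' Parse a reaction equation string
#'
#' Understands `"2 A[c] + B[c] -> C[e]"` style equations.  The token `->`
#' declares an irreversible reaction and `<=>` a reversible one; a missing
#' side denotes an exchange across the system boundary (e.g. `"-> A[c]"`
#' produces A).  Coefficients default to 1.
#'
#' @param text equation string.
#' @param row optional row number used in error messages.
#' @return list with `stoich` (named numeric, negative = consumed) and
#'   `reversible` (logical).
#' @export
parse_reaction_equation <- function(text, row = NA) {
  where <- if (is.na(row)) "" else sprintf(" (row %s)", row)
  text <- trimws(text)
  arrow <- if (grepl(ARROW_REV, text, fixed = TRUE)) ARROW_REV
           else if (grepl(ARROW_IRREV, text, fixed = TRUE)) ARROW_IRREV
           else NULL
  if (is.null(arrow)) {
    bad <- regmatches(text, regexpr("<->|=>|<=|<-", text))
    stop("equation", where, ": ",
         if (length(bad) > 0L) sprintf("unknown arrow token '%s'", bad)
         else "no arrow token ('->' or '<=>') found",
         call. = FALSE)
  }
  sides <- strsplit(text, arrow, fixed = TRUE)[[1L]]
  if (length(sides) > 2L) {
    stop("equation", where, ": more than one arrow token", call. = FALSE)
  }
  lhs <- parse_equation_side(if (length(sides) >= 1L) sides[1L] else "", where)
  rhs <- parse_equation_side(if (length(sides) == 2L) sides[2L] else "", where)
  stoich <- c(-lhs, rhs)
  if (length(stoich) > 0L) {
    stoich <- tapply(stoich, names(stoich), sum)   # net duplicated metabolites
    stoich <- stoich[abs(stoich) > 0]
    stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  }
  if (length(stoich) == 0L) {
    stop("equation", where, ": empty stoichiometry", call. = FALSE)
  }
  list(stoich = stoich, reversible = arrow == ARROW_REV)
}

parse_equation_side <- function(side, where) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(), character()))
  if (grepl("^\\+", side) || grepl("\\+$", side)) {
    stop("equation", where, ": empty term (stray '+')", call. = FALSE)
  }
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
  out <- numeric()
  for (term in terms) {
    if (!nzchar(term)) {
      stop("equation", where, ": empty term (stray '+')", call. = FALSE)
    }
    toks <- strsplit(term, "\\s+")[[1L]]
    if (length(toks) == 1L) {
      coef <- 1
      met <- toks[1L]
    } else if (length(toks) == 2L) {
      coef <- suppressWarnings(as.numeric(toks[1L]))
      if (is.na(coef)) {
        stop("equation", where, sprintf(": non-numeric coefficient '%s'",
                                        toks[1L]), call. = FALSE)
      }
      met <- toks[2L]
    } else {
      stop("equation", where, sprintf(": cannot parse term '%s'", term),
           call. = FALSE)
    }
    out <- c(out, stats::setNames(coef, met))
  }
  out
}

#' Format a stoichiometry as an equation string
#' @param stoich named numeric vector (negative = consumed).
#' @param reversible use the `<=>` arrow instead of `->`.
#' @export
format_reaction_equation <- function(stoich, reversible = FALSE) {
  fmt_side <- function(coefs) {
    if (length(coefs) == 0L) return("")
    paste(vapply(seq_along(coefs), function(i) {
      cf <- coefs[i]
      if (isTRUE(all.equal(cf, 1))) names(coefs)[i]
      else paste(format(cf, digits = 15, trim = TRUE), names(coefs)[i])
    }, character(1L)), collapse = " + ")
  }
  lhs <- fmt_side(-stoich[stoich < 0])
  rhs <- fmt_side(stoich[stoich > 0])
  trimws(paste(lhs, if (reversible) ARROW_REV else ARROW_IRREV, rhs))
}

# permissive header matching: lowercase, strip non-alphanumerics, then match
# against a list of accepted aliases
match_column <- function(headers, aliases, required = TRUE, what = aliases[1]) {
  norm <- gsub("[^a-z0-9]", "", tolower(headers))
  for (a in aliases) {
    hit <- which(norm == a)
    if (length(hit) > 0L) return(hit[1L])
  }
  if (required) {
    stop(sprintf("model CSV: no column matching '%s' (have: %s)",
                 what, paste(headers, collapse = ", ")), call. = FALSE)
  }
  NA_integer_
}

#' Read a metabolic model from a reaction-list CSV
#'
#' Expected columns (header names are matched permissively): reaction id,
#' name, equation/stoichiometry string, GPR string, lb, ub, and optionally a
#' biomass flag column.  Blank bounds default to `[0, 1000]` for `->`
#' reactions and `[-1000, 1000]` for `<=>` reactions.  If no biomass column
#' is present, a single reaction whose id or name contains "biomass"
#' (case-insensitively) is flagged.
#'
#' @param path CSV file path.
#' @param default_bound bound magnitude used when lb/ub cells are blank.
#' @return a [metabolic_model()].
#' @export
read_model_csv <- function(path, default_bound = 1000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  ci <- match_column(names(df), c("id", "reactionid", "rxnid", "reaction",
                                  "abbreviation"), what = "id")
  cn <- match_column(names(df), c("name", "reactionname", "description"),
                     required = FALSE)
  ce <- match_column(names(df), c("equation", "stoichiometry", "formula",
                                  "reactionformula"), what = "equation")
  cg <- match_column(names(df), c("gpr", "gprrule", "geneassociation",
                                  "genes", "grrule"), required = FALSE)
  clb <- match_column(names(df), c("lb", "lowerbound"), required = FALSE)
  cub <- match_column(names(df), c("ub", "upperbound"), required = FALSE)
  cb <- match_column(names(df), c("biomass", "isbiomass"), required = FALSE)
  seen <- character()
  reactions <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    id <- trimws(df[[ci]][i])
    if (!nzchar(id)) stop("model CSV row ", i, ": blank reaction id",
                          call. = FALSE)
    if (id %in% seen) stop("model CSV row ", i, ": duplicate reaction id '",
                           id, "'", call. = FALSE)
    seen <- c(seen, id)
    eq <- parse_reaction_equation(df[[ce]][i], row = i)
    lb <- if (eq$reversible) -default_bound else 0
    ub <- default_bound
    if (!is.na(clb) && nzchar(trimws(df[[clb]][i]))) {
      lb <- as.numeric(df[[clb]][i])
      if (is.na(lb)) stop("model CSV row ", i, ": non-numeric lb",
                          call. = FALSE)
    }
    if (!is.na(cub) && nzchar(trimws(df[[cub]][i]))) {
      ub <- as.numeric(df[[cub]][i])
      if (is.na(ub)) stop("model CSV row ", i, ": non-numeric ub",
                          call. = FALSE)
    }
    bio <- if (!is.na(cb)) tolower(trimws(df[[cb]][i])) %in%
             c("1", "true", "yes", "y") else FALSE
    reactions[[i]] <- reaction(
      id = id,
      name = if (!is.na(cn)) df[[cn]][i] else id,
      stoich = eq$stoich, lb = lb, ub = ub,
      gpr = if (!is.na(cg)) df[[cg]][i] else "",
      is_biomass = bio)
  }
  if (is.na(cb)) {
    hit <- which(vapply(reactions, function(r) {
      grepl("biomass", r$id, ignore.case = TRUE) ||
        grepl("biomass", r$name, ignore.case = TRUE)
    }, logical(1L)))
    if (length(hit) == 1L) reactions[[hit]]$is_biomass <- TRUE
  }
  metabolic_model(reactions, id = sub("\\.csv$", "", basename(path)))
}

#' Write a metabolic model as a reaction-list CSV
#'
#' Inverse of [read_model_csv()]: `read_model_csv(write_model_csv(m, f))`
#' reproduces the model up to numerical formatting.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @export
write_model_csv <- function(model, path) {
  rows <- lapply(model$reactions, function(r) {
    data.frame(id = r$id, name = r$name,
               equation = format_reaction_equation(r$stoich, r$lb < 0),
               gpr = format(r$gpr),
               lb = r$lb, ub = r$ub,
               biomass = if (r$is_biomass) "true" else "",
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a two-column expression TSV (gene id, value)
#' @param path TSV file with a header line.
#' @return named numeric vector of expression values.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read / write ternary call TSVs (id, call in {-1, 0, 1})
#'
#' Used both for gene calls (Table S1 style) and reaction calls (Table S3
#' style).
#' @param path TSV file with a header line.
#' @return named integer vector of calls.
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  calls <- as.integer(df[[2L]])
  if (any(!calls %in% c(-1L, 0L, 1L))) {
    stop("calls TSV: calls must be -1, 0 or 1", call. = FALSE)
  }
  stats::setNames(calls, as.character(df[[1L]]))
}

#' @rdname read_calls_tsv
#' @param calls named integer vector in {-1, 0, 1}.
#' @param id_col name of the id column in the header.
#' @export
write_calls_tsv <- function(calls, path, id_col = "id") {
  df <- data.frame(id = names(calls), call = as.integer(calls),
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reaction-frequency table (Table S4 style)
#' @param freq a `frequency_sets` object from [classify_frequencies()].
#' @param path output TSV.
#' @export
write_freq_tsv <- function(freq, path) {
  utils::write.table(freq$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reaction-frequency table written by [write_freq_tsv()]
#' @param path TSV path.
#' @return data.frame with columns `reaction`, `count`, `n_solutions`,
#'   `frequency`, `class`.
#' @export
read_freq_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a flux-state table (Table S5/S6 style)
#'
#' Reports reaction id, name, equation, associated genes and predicted flux;
#' reactions with `|v|` below `min_abs_flux` are omitted, matching the
#' published flux-state tables.
#'
#' @param model the `metabolic_model` the fluxes refer to.
#' @param flux named numeric flux vector.
#' @param path output TSV.
#' @param min_abs_flux suppression threshold (default 1e-10).
#' @export
write_flux_tsv <- function(model, flux, path, min_abs_flux = 1e-10) {
  ids <- reaction_ids(model)
  flux <- flux[ids]
  keep <- which(abs(flux) >= min_abs_flux)
  rows <- lapply(keep, function(j) {
    r <- model$reactions[[j]]
    data.frame(reaction = r$id, name = r$name,
               equation = format_reaction_equation(r$stoich, r$lb < 0),
               genes = paste(r$gpr$genes, collapse = ";"),
               flux = as.numeric(flux[j]), stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(reaction = character(), name = character(),
               equation = character(), genes = character(), flux = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-id-per-line gene list (observed essential genes etc.)
#' @param path text file, one gene id per line; blank lines and `#` comments
#'   are ignored.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
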