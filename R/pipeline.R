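# End-to-end driver: open + trim the model, discretize expression, solve the
# agreement-score MILP, explore alternative optima, classify HFR/ZFR, build
# the environment-specific context model, predict the flux state and the
# essential genes.  The file-based front end (run_pipeline) writes every
# intermediate in its documented format together with a run manifest.

#' Run the full expression-to-metabolic-state analysis
#'
#' @param model a `metabolic_model` with a designated biomass reaction.
#' @param expression gene-level input: an `expression_calls` object, a named
#'   ternary call vector, or a named numeric vector of continuous expression
#'   values (discretized with `hi_frac`/`lo_frac`).
#' @param hi_frac,lo_frac discretization fractions (default 0.15).
#' @param eps iMAT activation threshold (default 1.0).
#' @param bound_magnitude exchange bound magnitude (default 1000).
#' @param trim drop dead-end reactions before the analysis (default TRUE).
#' @param trim_tol blocked-reaction tolerance (default 1e-9).
#' @param activity_tol activity threshold for frequency counting
#'   (default 1e-6).
#' @param seed seed for the pruning order (default 0).
#' @param growth_tol FBA growth threshold for essentiality (default 1e-6).
#' @param observed_essential optional character vector of genes observed
#'   essential, scored against the predictions.
#' @param excluded_genes genes excluded from essentiality scoring.
#' @return an `examo` object: list with `model` (opened, trimmed parent),
#'   `expression`, `calls` (reaction calls), `imat`, `ensemble`, `freq`,
#'   `context`, `flux_state`, `essentiality` (per-gene data.frame),
#'   `report` (an `essentiality_report` or NULL) and `manifest`.
#' @export
examo <- function(model, expression, hi_frac = 0.15, lo_frac = 0.15,
                  eps = 1, bound_magnitude = 1000, trim = TRUE,
                  trim_tol = 1e-9, activity_tol = 1e-6, seed = 0,
                  growth_tol = 1e-6, observed_essential = NULL,
                  excluded_genes = character()) {
  stopifnot(inherits(model, "metabolic_model"))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }
  model <- stage("open", open_exchanges(model, bound_magnitude))
  if (trim) model <- stage("trim", trim_dead_ends(model, tol = trim_tol))
  expression <- if (is.numeric(expression) &&
                    !all(expression %in% c(-1, 0, 1))) {
    call_genes(expression, hi_frac = hi_frac, lo_frac = lo_frac)
  } else {
    as_expression_calls(expression, hi_frac, lo_frac)
  }
  calls <- stage("calls", call_reactions(model, expression))
  problem <- imat_problem(model, calls, eps = eps)
  fit <- stage("imat", solve_imat(problem))
  ensemble <- stage("explore", explore_optima(problem,
                                              activity_tol = activity_tol))
  freq <- classify_frequencies(ensemble)
  context <- stage("build", build_context_model(model, freq, seed = seed))
  flux_state <- stage("minflux",
                      minimize_total_flux(context$model, freq$HFR, eps = eps))
  essentiality <- stage("essentiality",
                        predict_essential_genes(context$model,
                                                growth_tol = growth_tol))
  report <- NULL
  if (!is.null(observed_essential)) {
    universe <- union(union(context$model$genes, observed_essential),
                      excluded_genes)
    report <- essentiality_metrics(
      predicted = essentiality$gene[essentiality$essential],
      observed = observed_essential, universe = universe,
      excluded = excluded_genes)
  }
  manifest <- list(
    tool = paste0("examo ", as.character(utils::packageVersion("examo"))),
    parameters = list(hi_frac = hi_frac, lo_frac = lo_frac, eps = eps,
                      bound_magnitude = bound_magnitude, trim = trim,
                      trim_tol = trim_tol, activity_tol = activity_tol,
                      seed = seed, growth_tol = growth_tol),
    stage_seconds = as.list(timings),
    sizes = list(reactions = length(model$reactions),
                 rH = length(calls$rH), rL = length(calls$rL),
                 score = fit$score,
                 optima_retained = length(ensemble$solutions),
                 optima_distinct = ensemble$distinct_count,
                 HFR = length(freq$HFR), ZFR = length(freq$ZFR),
                 context_reactions = length(context$model$reactions)))
  structure(list(model = model, expression = expression, calls = calls,
                 imat = fit, ensemble = ensemble, freq = freq,
                 context = context, flux_state = flux_state,
                 essentiality = essentiality, report = report,
                 manifest = manifest),
            class = "examo")
}

#' @export
print.examo <- function(x, ...) {
  s <- x$manifest$sizes
  cat("<examo> ", s$reactions, " reactions after trimming; |rH| = ", s$rH,
      ", |rL| = ", s$rL, "\n", sep = "")
  cat("  agreement score ", s$score, " over ", s$optima_retained,
      " retained optima (", s$optima_distinct, " distinct)\n", sep = "")
  cat("  |HFR| = ", s$HFR, ", |ZFR| = ", s$ZFR, "; context model: ",
      s$context_reactions, " reactions\n", sep = "")
  cat("  total flux ", format(x$flux_state$total_flux), "; ",
      sum(x$essentiality$essential), " predicted essential genes\n",
      sep = "")
  if (!is.null(x$report)) {
    cat("  validation: sensitivity ",
        sprintf("%.1f%%", 100 * x$report$sensitivity), ", PPV ",
        sprintf("%.1f%%", 100 * x$report$ppv), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.examo <- function(object, ...) {
  print(object)
  cat("\nStage timings (s):\n")
  t <- object$manifest$stage_seconds
  for (nm in names(t)) cat(sprintf("  %-12s %s\n", nm, t[[nm]]))
  ft <- object$freq$table
  inter <- ft[ft$class == "intermediate", , drop = FALSE]
  cat("\nIntermediate-frequency reactions: ", nrow(inter), "\n", sep = "")
  invisible(object)
}

#' Run the pipeline from files, writing all artifacts and a manifest
#'
#' @param config named list (or path to a flat `key = value` config file)
#'   with entries `model` (reaction-list CSV), `expression` (TSV of values
#'   or of ternary calls), optional `observed_essential` /
#'   `excluded_genes` (gene-list files), and any of the [examo()] parameter
#'   names.
#' @param out_dir output directory (created if needed).
#' @return the `examo` object, invisibly; artifacts written: `trimmed.csv`,
#'   `gene_calls.tsv`, `reaction_calls.tsv`, `imat_flux.tsv`, `freq.tsv`,
#'   `context.csv`, `state.tsv`, `essentiality.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  stopifnot(is.list(config), !is.null(config$model),
            !is.null(config$expression))
  for (f in c("model", "expression")) {
    if (!file.exists(config[[f]])) {
      stop("run_pipeline: ", f, " file not found: ", config[[f]],
           call. = FALSE)
    }
  }
  inputs <- c(model = config$model, expression = config$expression)
  model <- read_model_csv(config$model)
  expr_df <- utils::read.delim(config$expression, stringsAsFactors = FALSE)
  expr <- stats::setNames(as.numeric(expr_df[[2L]]),
                          as.character(expr_df[[1L]]))
  observed <- NULL
  if (!is.null(config$observed_essential)) {
    observed <- read_gene_list(config$observed_essential)
    inputs <- c(inputs, observed_essential = config$observed_essential)
  }
  excluded <- character()
  if (!is.null(config$excluded_genes)) {
    excluded <- read_gene_list(config$excluded_genes)
    inputs <- c(inputs, excluded_genes = config$excluded_genes)
  }
  num <- function(key, default) {
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  }
  fit <- examo(model, expr,
               hi_frac = num("hi_frac", 0.15), lo_frac = num("lo_frac", 0.15),
               eps = num("eps", 1), bound_magnitude = num("bound", 1000),
               trim_tol = num("trim_tol", 1e-9),
               activity_tol = num("activity_tol", 1e-6),
               seed = num("seed", 0), growth_tol = num("growth_tol", 1e-6),
               observed_essential = observed, excluded_genes = excluded)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)
  write_model_csv(fit$model, out("trimmed.csv"))
  write_calls_tsv(fit$expression$calls, out("gene_calls.tsv"),
                  id_col = "gene")
  write_calls_tsv(fit$calls$calls, out("reaction_calls.tsv"),
                  id_col = "reaction")
  write_flux_tsv(fit$model, fit$imat$flux, out("imat_flux.tsv"))
  write_freq_tsv(fit$freq, out("freq.tsv"))
  write_model_csv(fit$context$model, out("context.csv"))
  write_flux_tsv(fit$context$model, fit$flux_state$flux, out("state.tsv"))
  ess <- fit$essentiality
  utils::write.table(ess, out("essentiality.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- c(fit$manifest,
                list(inputs = as.list(stats::setNames(
                       tools::md5sum(as.character(inputs)), names(inputs))),
                     config = config))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(fit)
}

# flat "key = value" config files; '#' starts a comment
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) {
      stop("config: cannot parse line '", ln, "'", call. = FALSE)
    }
    out[[trimws(kv[1L])]] <- trimws(paste(kv[-1L], collapse = "="))
  }
  out
}
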