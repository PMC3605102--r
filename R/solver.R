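# Internal LP/MILP layer.  All linear and mixed-integer programs in the
# package are solved exactly (zero relative MIP gap) with HiGHS, reached
# through a small bundled Python helper so that many programs can be solved
# per interpreter start-up.  Problems and results travel as JSON.

#' @noRd
examo_python <- function() {
  py <- getOption("examo.python", Sys.getenv("EXAMO_PYTHON", "python"))
  path <- Sys.which(py)
  if (!nzchar(path)) {
    stop("No `python` interpreter found on PATH; set options(examo.python=) ",
         "or the EXAMO_PYTHON environment variable.", call. = FALSE)
  }
  path
}

#' Assemble one linear/mixed-integer program
#'
#' Internal canonical form: minimize or maximize `obj` %*% x subject to
#' `con_lb <= A %*% x <= con_ub` and `lb <= x <= ub`, with `integrality`
#' marking integer variables (0 = continuous, 1 = integer).
#' Infinite bounds are allowed.
#' @noRd
milp_problem <- function(obj, A = NULL, con_lb = NULL, con_ub = NULL,
                         lb, ub, integrality = NULL, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (is.null(integrality)) integrality <- integer(n)
  if (!is.null(A)) {
    A <- as.matrix(A)
    stopifnot(ncol(A) == n, nrow(A) == length(con_lb),
              nrow(A) == length(con_ub))
  }
  list(obj = as.numeric(obj), A = A,
       con_lb = as.numeric(con_lb), con_ub = as.numeric(con_ub),
       lb = as.numeric(lb), ub = as.numeric(ub),
       integrality = as.integer(integrality), maximize = isTRUE(maximize))
}

# JSON cannot carry Inf; encode as +/-1e30, decoded by the helper.
.encode_inf <- function(x) {
  x[is.infinite(x) & x > 0] <- 1e30
  x[is.infinite(x) & x < 0] <- -1e30
  x
}

#' Solve a batch of LP/MILP problems in one solver process
#'
#' @param problems list of problems from [milp_problem()].
#' @return list of results, each with elements `status` (0 = optimal,
#'   2 = infeasible, 3 = unbounded), `success`, `x`, `objective`, `message`.
#' @noRd
milp_solve_batch <- function(problems) {
  if (length(problems) == 0L) return(list())
  script <- system.file("python", "milp_batch.py", package = "examo",
                        mustWork = TRUE)
  payload <- lapply(problems, function(p) {
    list(obj = p$obj,
         A = p$A,  # matrices serialize as nested row-major arrays
         con_lb = .encode_inf(p$con_lb), con_ub = .encode_inf(p$con_ub),
         lb = .encode_inf(p$lb), ub = .encode_inf(p$ub),
         integrality = p$integrality, maximize = p$maximize)
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = TRUE,
                       null = "null")
  code <- system2(examo_python(), c(script, fin, fout),
                  stdout = FALSE, stderr = "")
  if (code != 0L || !file.exists(fout)) {
    stop("MILP solver helper failed (exit code ", code, ")", call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  lapply(res, function(r) {
    r$x <- if (is.null(r$x)) NULL else as.numeric(unlist(r$x))
    r
  })
}

#' @noRd
milp_solve <- function(problem) milp_solve_batch(list(problem))[[1L]]
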