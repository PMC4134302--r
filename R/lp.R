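#' Solve a linear program
#'
#' Minimal interface to the bundled dense bounded-variable simplex. All
#' variables carry explicit (possibly infinite) bounds; constraint rows are
#' given as a dense matrix with a direction per row.
#'
#' @param obj numeric objective coefficients, one per variable.
#' @param mat dense constraint matrix (rows = constraints).
#' @param dir character vector of row directions, each one of `"<="`,
#'   `"=="`, `">="`.
#' @param rhs numeric right-hand sides.
#' @param lower,upper variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize maximize instead of minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iterlimit"`), `x` (solution or `NA`), `objval`.
#' @export
solve_lp <- function(obj, mat, dir, rhs, lower, upper, maximize = FALSE) {
  mat <- as.matrix(mat)
  stopifnot(length(obj) == ncol(mat), length(rhs) == nrow(mat),
            length(dir) == nrow(mat),
            length(lower) == ncol(mat), length(upper) == ncol(mat))
  sense <- match(dir, c("<=", "==", ">=")) - 2L
  if (anyNA(sense)) stop("row directions must be one of '<=', '==', '>='")
  res <- .cpp_solve_lp(as.numeric(obj), mat, sense, as.numeric(rhs),
                       as.numeric(lower), as.numeric(upper), maximize)
  res$status <- c("optimal", "infeasible", "unbounded", "iterlimit")[res$status + 1L]
  res
}

#' Solve a mixed-integer linear program
#'
#' Branch and bound over the bundled simplex. Integer variables are expected
#' to be binaries (bounds within \[0, 1\]); branching fixes them.
#'
#' @inheritParams solve_lp
#' @param int_vars indices (1-based) of integer-constrained variables.
#' @param obj_integral set when the objective provably takes integer values
#'   at integer solutions; enables rounding-based pruning.
#' @param node_limit search-node budget before aborting.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"nodelimit"`),
#'   `x`, `objval`, `nodes`.
#' @export
solve_milp <- function(obj, mat, dir, rhs, lower, upper, int_vars = integer(),
                       maximize = FALSE, obj_integral = FALSE,
                       node_limit = 2e5) {
  mat <- as.matrix(mat)
  stopifnot(length(obj) == ncol(mat), length(rhs) == nrow(mat))
  sense <- match(dir, c("<=", "==", ">=")) - 2L
  if (anyNA(sense)) stop("row directions must be one of '<=', '==', '>='")
  res <- .cpp_solve_milp(as.numeric(obj), mat, sense, as.numeric(rhs),
                         as.numeric(lower), as.numeric(upper),
                         as.integer(int_vars) - 1L, maximize, obj_integral,
                         as.numeric(node_limit))
  res$status <- switch(as.character(res$status),
                       "0" = "optimal", "1" = "infeasible",
                       "4" = "nodelimit", "5" = "nodelimit")
  if (identical(res$status, "nodelimit"))
    stop("MILP node limit reached; incumbent objective: ", res$objval)
  res
}
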