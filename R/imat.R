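#' Define an iMAT consistency-maximization problem
#'
#' @param model a `metabolic_model`.
#' @param R_H character vector of reaction ids cued highly expressed.
#' @param R_L character vector of reaction ids cued lowly expressed.
#' @param epsilon activation flux threshold: a reaction counts as active
#'   when `|v| >= epsilon`. Default 1 in bound units of 1000.
#' @return object of class `imat_problem`.
#' @export
imat_problem <- function(model, R_H = character(), R_L = character(),
                         epsilon = 1) {
  stopifnot(epsilon > 0)
  rids <- model$reactions$id
  bad <- setdiff(c(R_H, R_L), rids)
  if (length(bad)) stop("unknown cued reaction: ", paste(bad, collapse = ", "))
  if (length(intersect(R_H, R_L)))
    stop("R_H and R_L overlap: ",
         paste(intersect(R_H, R_L), collapse = ", "))
  structure(list(model = model, R_H = unique(R_H), R_L = unique(R_L),
                 epsilon = epsilon),
            class = "imat_problem")
}

# Assemble the iMAT MILP. Variables are the n fluxes followed by the
# activity binaries; big-M constants come from each reaction's own bounds.
# For i in R_H a forward binary forces v_i >= eps and (for reversible
# reactions) a backward binary forces v_i <= -eps, at most one of the two
# set. For i in R_L a binary forces lb(1-y) <= v_i <= ub(1-y), i.e. v = 0.
build_imat_milp <- function(model, R_H, R_L, epsilon) {
  rx <- model$reactions
  n <- nrow(rx)
  rid <- rx$id
  S <- stoichiometric_matrix(model)

  vars <- rid
  lo <- rx$lb; hi <- rx$ub
  obj <- rep(0, n)
  rows <- list(); dirs <- character(); rhs <- numeric()
  add_row <- function(coef, dir, b) {
    rows[[length(rows) + 1L]] <<- coef
    dirs[length(dirs) + 1L] <<- dir
    rhs[length(rhs) + 1L] <<- b
  }
  bin_of <- list() # reaction id -> binary column indices

  for (r in R_H) {
    i <- match(r, rid)
    cols <- integer()
    if (rx$ub[i] >= epsilon) {            # forward activation
      vars <- c(vars, paste0("yf_", r)); lo <- c(lo, 0); hi <- c(hi, 1)
      obj <- c(obj, 1)
      j <- length(vars)
      add_row(c(stats::setNames(1, i), stats::setNames(rx$lb[i] - epsilon, j)),
              ">=", rx$lb[i])
      cols <- c(cols, j)
    }
    if (rx$lb[i] <= -epsilon) {           # backward activation
      vars <- c(vars, paste0("yb_", r)); lo <- c(lo, 0); hi <- c(hi, 1)
      obj <- c(obj, 1)
      j <- length(vars)
      add_row(c(stats::setNames(1, i), stats::setNames(rx$ub[i] + epsilon, j)),
              "<=", rx$ub[i])
      cols <- c(cols, j)
    }
    if (length(cols) == 2L)
      add_row(stats::setNames(c(1, 1), cols), "<=", 1)
    bin_of[[r]] <- cols
  }
  for (r in R_L) {
    i <- match(r, rid)
    vars <- c(vars, paste0("y_", r)); lo <- c(lo, 0); hi <- c(hi, 1)
    obj <- c(obj, 1)
    j <- length(vars)
    if (rx$lb[i] != 0)
      add_row(c(stats::setNames(1, i), stats::setNames(rx$lb[i], j)),
              ">=", rx$lb[i])
    if (rx$ub[i] != 0)
      add_row(c(stats::setNames(1, i), stats::setNames(rx$ub[i], j)),
              "<=", rx$ub[i])
    bin_of[[r]] <- j
  }

  ntot <- length(vars)
  nrows <- nrow(S) + length(rows)
  mat <- matrix(0, nrow = nrows, ncol = ntot)
  mat[seq_len(nrow(S)), seq_len(n)] <- S
  dir <- c(rep("==", nrow(S)), dirs)
  b <- c(rep(0, nrow(S)), rhs)
  for (k in seq_along(rows)) {
    coef <- rows[[k]]
    mat[nrow(S) + k, as.integer(names(coef))] <- coef
  }
  list(obj = obj, mat = mat, dir = dir, rhs = b, lower = lo, upper = hi,
       int_vars = seq.int(n + 1L, length.out = ntot - n),
       vars = vars, n = n, bin_of = bin_of)
}

#' Solve the iMAT problem
#'
#' Finds a steady-state flux distribution maximizing the number of R_H
#' reactions carrying activating flux (`|v| >= epsilon`) plus R_L
#' reactions carrying zero flux, as a mixed-integer linear program.
#'
#' @param problem an [imat_problem()].
#' @return object of class `imat_solution`: `flux` (named vector),
#'   `active` (named logical, `|v| >= epsilon - 1e-6`), `objective`
#'   (integer count of satisfied cues), `status`, `satisfied` (named
#'   logical over cued reactions), plus the problem's cue sets.
#' @export
solve_imat <- function(problem) {
  stopifnot(inherits(problem, "imat_problem"))
  model <- problem$model
  p <- build_imat_milp(model, problem$R_H, problem$R_L, problem$epsilon)
  res <- solve_milp(p$obj, p$mat, p$dir, p$rhs, p$lower, p$upper,
                    int_vars = p$int_vars, maximize = TRUE,
                    obj_integral = TRUE)
  if (!identical(res$status, "optimal"))
    return(structure(list(flux = NULL, active = NULL, objective = NA_integer_,
                          status = "infeasible", epsilon = problem$epsilon,
                          R_H = problem$R_H, R_L = problem$R_L),
                     class = "imat_solution"))
  flux <- stats::setNames(res$x[seq_len(p$n)], model$reactions$id)
  flux[abs(flux) < 1e-9] <- 0
  satisfied <- vapply(c(problem$R_H, problem$R_L), function(r) {
    cols <- p$bin_of[[r]]
    length(cols) > 0L && sum(res$x[cols]) > 0.5
  }, TRUE)
  structure(list(
    flux = flux,
    active = abs(flux) >= problem$epsilon - 1e-6,
    objective = as.integer(round(res$objval)),
    status = "optimal",
    satisfied = satisfied,
    epsilon = problem$epsilon,
    R_H = problem$R_H, R_L = problem$R_L),
    class = "imat_solution")
}

#' @export
print.imat_solution <- function(x, ...) {
  cat("imat_solution:", x$status, "| objective", x$objective, "of",
      length(x$R_H) + length(x$R_L), "cues |",
      sum(x$active), "active reactions\n")
  invisible(x)
}

#' Brute-force iMAT oracle
#'
#' Enumerates every assignment of cue satisfaction (and flux direction for
#' reversible highly-cued reactions) in decreasing order of satisfied-cue
#' count and checks each by LP feasibility with tightened bounds; the
#' first feasible assignment is optimal. Independent of the MILP path;
#' intended for testing on small instances.
#'
#' @param problem an [imat_problem()] with at most 12 cued reactions.
#' @return list with `objective`, `flux`, `active` as in
#'   [solve_imat()].
#' @export
brute_force_imat <- function(problem) {
  stopifnot(inherits(problem, "imat_problem"))
  model <- problem$model
  eps <- problem$epsilon
  cues <- c(problem$R_H, problem$R_L)
  ncue <- length(cues)
  if (ncue > 12L) stop("brute_force_imat: more than 12 cued reactions")
  rx <- model$reactions
  S <- stoichiometric_matrix(model)
  n <- nrow(rx)
  dirs <- rep("==", nrow(S)); b <- rep(0, nrow(S)); objv <- rep(0, n)
  is_high <- cues %in% problem$R_H

  try_assignment <- function(sat) {
    lo <- rx$lb; hi <- rx$ub
    # direction options for each satisfied high cue
    opts <- lapply(seq_len(ncue), function(k) {
      if (!sat[k]) return(list(NULL))
      i <- match(cues[k], rx$id)
      if (is_high[k]) {
        o <- list()
        if (rx$ub[i] >= eps) o <- c(o, list(c(i, 1)))
        if (rx$lb[i] <= -eps) o <- c(o, list(c(i, -1)))
        if (!length(o)) return(NULL) # cue unsatisfiable
        o
      } else list(c(i, 0))
    })
    if (any(vapply(opts, is.null, TRUE))) return(NULL)
    combo_grid <- expand.grid(lapply(opts, seq_along))
    for (g in seq_len(nrow(combo_grid))) {
      lo2 <- lo; hi2 <- hi; ok <- TRUE
      for (k in seq_len(ncue)) {
        ch <- opts[[k]][[combo_grid[g, k]]]
        if (is.null(ch)) next
        i <- ch[1]
        if (ch[2] == 1) lo2[i] <- max(lo2[i], eps)
        else if (ch[2] == -1) hi2[i] <- min(hi2[i], -eps)
        else { lo2[i] <- 0; hi2[i] <- 0 }
        if (lo2[i] > hi2[i]) { ok <- FALSE; break }
      }
      if (!ok) next
      res <- solve_lp(objv, S, dirs, b, lo2, hi2, maximize = FALSE)
      if (identical(res$status, "optimal")) return(res$x)
    }
    NULL
  }

  for (size in rev(0:ncue)) {
    subsets <- if (size == 0L) list(integer()) else
      utils::combn(ncue, size, simplify = FALSE)
    for (idx in subsets) {
      sat <- rep(FALSE, ncue); sat[idx] <- TRUE
      x <- try_assignment(sat)
      if (!is.null(x)) {
        flux <- stats::setNames(x[seq_len(n)], rx$id)
        flux[abs(flux) < 1e-9] <- 0
        return(list(objective = size, flux = flux,
                    active = abs(flux) >= eps - 1e-6))
      }
    }
  }
  stop("no feasible assignment found (v = 0 should always be feasible)")
}

#' Call post-transcriptional regulation flags
#'
#' Compares each reaction's expression cue with its predicted activity in
#' an optimal iMAT solution: a lowly-cued but active reaction is called
#' post-transcriptionally up-regulated; a highly-cued but inactive one,
#' down-regulated.
#'
#' @param states named integer vector of reaction cue levels.
#' @param solution an optimal `imat_solution`.
#' @return named character vector with values `"up"`, `"down"`, `"none"`.
#' @export
detect_ptr <- function(states, solution) {
  stopifnot(inherits(solution, "imat_solution"),
            identical(solution$status, "optimal"))
  act <- solution$active[names(states)]
  out <- rep("none", length(states))
  out[states == -1L & act] <- "up"
  out[states == 1L & !act] <- "down"
  stats::setNames(out, names(states))
}
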