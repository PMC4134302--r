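#' Flux variability analysis under the iMAT-optimal state
#'
#' Computes, for each reaction, the minimum and maximum flux over the iMAT
#' feasible set with the consistency objective locked to its optimum
#' (`lock = TRUE`, the default; the objective is integral so the lock is
#' exact, with an optional integer slack for sensitivity analysis). With
#' `lock = FALSE` plain stoichiometric FVA over the bounds is returned.
#'
#' @param model a `metabolic_model`.
#' @param problem an [imat_problem()]; may be omitted when `lock = FALSE`.
#' @param lock constrain the consistency objective to its optimum.
#' @param solution optional precomputed [solve_imat()] result.
#' @param reactions reaction ids to scan (default: all).
#' @param slack integer slack on the locked objective (optimum - slack).
#' @return data.frame with columns `reaction`, `min`, `max`; failed
#'   per-reaction solves yield `NA` with a warning.
#' @export
fva <- function(model, problem = NULL, lock = TRUE, solution = NULL,
                reactions = NULL, slack = 0L) {
  if (is.null(problem))
    problem <- imat_problem(model)
  stopifnot(inherits(problem, "imat_problem"))
  rids <- if (is.null(reactions)) model$reactions$id else reactions
  p <- build_imat_milp(model, problem$R_H, problem$R_L, problem$epsilon)
  mat <- p$mat; dir <- p$dir; rhs <- p$rhs
  if (lock && length(p$int_vars)) {
    if (is.null(solution)) solution <- solve_imat(problem)
    if (!identical(solution$status, "optimal"))
      stop("cannot lock FVA: iMAT solve was not optimal")
    lockrow <- rep(0, ncol(mat)); lockrow[p$int_vars] <- 1
    mat <- rbind(mat, lockrow)
    dir <- c(dir, ">=")
    rhs <- c(rhs, solution$objective - slack)
  }
  res <- data.frame(reaction = rids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(rids)) {
    j <- match(rids[k], model$reactions$id)
    obj <- rep(0, ncol(mat)); obj[j] <- 1
    for (side in c("min", "max")) {
      val <- tryCatch({
        r <- solve_milp(obj, mat, dir, rhs, p$lower, p$upper,
                        int_vars = p$int_vars, maximize = side == "max",
                        obj_integral = FALSE)
        if (!identical(r$status, "optimal")) stop(r$status)
        r$objval
      }, error = function(e) {
        warning("FVA failed for reaction '", rids[k], "' (", side, "): ",
                conditionMessage(e))
        NA_real_
      })
      res[[side]][k] <- if (is.na(val)) NA_real_ else
        if (abs(val) < 1e-9) 0 else val
    }
  }
  res
}

#' Compare two flux intervals by the printed ordering rule
#'
#' For intervals `A = [minA, maxA]`, `B = [minB, maxB]`, `A < B` holds
#' when `((minA < minB) & (maxA <= maxB)) | ((minA <= minB) & (maxA <
#' maxB))`, and symmetrically for `B < A`. A difference is significant
#' only when the smaller interval is at least `delta` (default 90%) lower
#' than the larger: on interval maxima for the positive (secretion) side,
#' on absolute minima for the negative (uptake) side; intervals straddling
#' zero are judged on the larger-magnitude side.
#'
#' @param A,B numeric length-2 vectors `c(min, max)`.
#' @param delta significance fraction in \[0, 1).
#' @return list with `relation` (`"A_less"`, `"B_less"`, `"none"`),
#'   `significant`, `delta`.
#' @export
compare_intervals <- function(A, B, delta = 0.9) {
  le_tol <- function(a, b) a <= b + 1e-9 * (1 + abs(b))
  stopifnot(length(A) == 2L, length(B) == 2L, delta >= 0, delta < 1,
            A[1] <= A[2] + 1e-12, B[1] <= B[2] + 1e-12)
  a_less <- (A[1] < B[1] && A[2] <= B[2]) || (A[1] <= B[1] && A[2] < B[2])
  b_less <- (B[1] < A[1] && B[2] <= A[2]) || (B[1] <= A[1] && B[2] < A[2])
  relation <- if (a_less) "A_less" else if (b_less) "B_less" else "none"
  significant <- FALSE
  if (relation != "none") {
    pos_mag <- max(A[2], B[2], 0)
    neg_mag <- max(-A[1], -B[1], 0)
    lo <- if (relation == "A_less") A else B  # the ordered-lower interval
    hi <- if (relation == "A_less") B else A
    if (pos_mag >= neg_mag && pos_mag > 0) {
      # positive side: the lower interval has the smaller maximum
      significant <- le_tol(max(lo[2], 0), (1 - delta) * max(hi[2], 0))
    } else if (neg_mag > 0) {
      # negative side: the lower interval reaches further below zero,
      # so the *higher* interval is the small-magnitude one
      significant <- le_tol(max(-hi[1], 0), (1 - delta) * max(-lo[1], 0))
    }
  }
  list(relation = relation, significant = significant, delta = delta)
}

#' Reactions whose flux interval is altered between conditions
#'
#' @param control,disease data.frames from [fva()] over the same reaction
#'   universe.
#' @param delta significance fraction (default 0.9).
#' @return data.frame with columns `reaction`, `direction`
#'   (`"decreased"`/`"increased"` in disease), `relation`.
#' @export
altered_reactions <- function(control, disease, delta = 0.9) {
  if (!setequal(control$reaction, disease$reaction))
    stop("control and disease intervals cover different reactions")
  disease <- disease[match(control$reaction, disease$reaction), ]
  out <- list()
  for (k in seq_len(nrow(control))) {
    A <- c(control$min[k], control$max[k])
    B <- c(disease$min[k], disease$max[k])
    if (anyNA(A) || anyNA(B)) next
    cmp <- compare_intervals(A, B, delta)
    if (!cmp$significant) next
    out[[length(out) + 1L]] <- data.frame(
      reaction = control$reaction[k],
      direction = if (cmp$relation == "B_less") "decreased" else "increased",
      relation = cmp$relation, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(reaction = character(), direction = character(),
                      relation = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Call exchange-metabolite biomarkers from interval changes
#'
#' For every exchange reaction whose control/disease intervals differ
#' significantly (see [compare_intervals()]), the change is classified by
#' which side of zero moved: the positive range is secretion, the negative
#' range uptake (model sign convention), and a reaction altered on both
#' sides yields two calls. Confidence is `"high"` when the two intervals
#' are disjoint, `"standard"` otherwise.
#'
#' @inheritParams altered_reactions
#' @param model the `metabolic_model` flagging exchange reactions.
#' @return data.frame with columns `metabolite`, `reaction`, `direction`
#'   (one of `secretion_increase`, `secretion_decrease`,
#'   `uptake_increase`, `uptake_decrease`), `confidence`.
#' @export
call_biomarkers <- function(control, disease, model, delta = 0.9) {
  ex <- model$reactions$id[model$reactions$exchange]
  out <- list()
  for (rid in intersect(ex, control$reaction)) {
    kc <- match(rid, control$reaction); kd <- match(rid, disease$reaction)
    if (is.na(kd)) next
    A <- c(control$min[kc], control$max[kc])
    B <- c(disease$min[kd], disease$max[kd])
    if (anyNA(A) || anyNA(B)) next
    cmp <- compare_intervals(A, B, delta)
    if (!cmp$significant) next
    confidence <- if (A[2] < B[1] || B[2] < A[1]) "high" else "standard"
    met <- names(model$stoich[[rid]])
    le_tol <- function(a, b) a <= b + 1e-9 * (1 + abs(b))
    dirs <- character()
    mc <- max(A[2], 0); md <- max(B[2], 0)   # secretion capacity
    if (max(mc, md) > 0) {
      if (md < mc && le_tol(md, (1 - delta) * mc))
        dirs <- c(dirs, "secretion_decrease")
      else if (mc < md && le_tol(mc, (1 - delta) * md))
        dirs <- c(dirs, "secretion_increase")
    }
    uc <- max(-A[1], 0); ud <- max(-B[1], 0) # uptake capacity
    if (max(uc, ud) > 0) {
      if (ud < uc && le_tol(ud, (1 - delta) * uc))
        dirs <- c(dirs, "uptake_decrease")
      else if (uc < ud && le_tol(uc, (1 - delta) * ud))
        dirs <- c(dirs, "uptake_increase")
    }
    for (d in dirs)
      out[[length(out) + 1L]] <- data.frame(
        metabolite = met, reaction = rid, direction = d,
        confidence = confidence, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(metabolite = character(), reaction = character(),
                      direction = character(), confidence = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Intersect two biomarker call lists
#'
#' Metabolites called in both analyses, with each context's direction
#' retained (the directions need not agree).
#'
#' @param calls_A,calls_B data.frames from [call_biomarkers()].
#' @param labels length-2 character vector naming the two contexts.
#' @return data.frame with columns `metabolite`, `direction_<label1>`,
#'   `direction_<label2>`.
#' @export
intersect_biomarker_calls <- function(calls_A, calls_B,
                                      labels = c("A", "B")) {
  shared <- intersect(calls_A$metabolite, calls_B$metabolite)
  collapse <- function(calls, met)
    paste(sort(unique(calls$direction[calls$metabolite == met])),
          collapse = "; ")
  out <- data.frame(metabolite = shared, stringsAsFactors = FALSE)
  out[[paste0("direction_", labels[1])]] <-
    vapply(shared, collapse, "", calls = calls_A)
  out[[paste0("direction_", labels[2])]] <-
    vapply(shared, collapse, "", calls = calls_B)
  out
}
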