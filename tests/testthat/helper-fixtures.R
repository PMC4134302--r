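# Shared fixtures and independent oracles for the test suite.

# --- tiny models built in code -------------------------------------------

# EX_A <-> A -> B <-> EX_B
chain_model <- function(lb_r1 = 0) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B"), name = c("A", "B"),
                             compartment = "c"),
    reactions = data.frame(
      id = c("EX_A", "R1", "EX_B"),
      lb = c(-1000, lb_r1, -1000), ub = 1000,
      gpr = c("", "g1", ""), pathway = c("", "Core", ""),
      exchange = c(TRUE, FALSE, TRUE)),
    stoich = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                  EX_B = c(B = -1)))
}

# source splits into two routable branches
branch_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("S", "P", "Q"),
                             name = c("S", "P", "Q"), compartment = "c"),
    reactions = data.frame(
      id = c("EX_S", "B1", "B2", "EX_P", "EX_Q"),
      lb = c(-1000, 0, 0, -1000, -1000), ub = 1000,
      gpr = c("", "g1", "g2", "", ""),
      pathway = c("", "Br1", "Br2", "", ""),
      exchange = c(TRUE, FALSE, FALSE, TRUE, TRUE)),
    stoich = list(EX_S = c(S = -1), B1 = c(S = -1, P = 1),
                  B2 = c(S = -1, Q = 1), EX_P = c(P = -1),
                  EX_Q = c(Q = -1)))
}

write_tmp_json <- function(model) {
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  path
}

# --- independent LP oracle: vertex enumeration ---------------------------
# For problems with all-finite variable bounds: every basic feasible point
# is the solution of n active constraints chosen among rows and bounds.
lp_vertex_oracle <- function(obj, mat, dir, rhs, lower, upper,
                             maximize = FALSE, tol = 1e-7) {
  n <- ncol(mat)
  A <- list(); b <- numeric(); eq <- logical()
  for (i in seq_len(nrow(mat))) {
    A[[length(A) + 1L]] <- mat[i, ]; b <- c(b, rhs[i])
    eq <- c(eq, dir[i] == "==")
  }
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    A[[length(A) + 1L]] <- e; b <- c(b, lower[j]); eq <- c(eq, FALSE)
    A[[length(A) + 1L]] <- e; b <- c(b, upper[j]); eq <- c(eq, FALSE)
  }
  feasible <- function(x) {
    for (i in seq_len(nrow(mat))) {
      v <- sum(mat[i, ] * x)
      ok <- switch(dir[i],
                   "<=" = v <= rhs[i] + tol,
                   ">=" = v >= rhs[i] - tol,
                   "==" = abs(v - rhs[i]) <= tol)
      if (!ok) return(FALSE)
    }
    all(x >= lower - tol) && all(x <= upper + tol)
  }
  m <- length(A)
  best <- NULL
  for (combo in utils::combn(m, n, simplify = FALSE)) {
    if (any(eq) && !all(which(eq) %in% combo)) next
    M <- do.call(rbind, A[combo])
    if (abs(det(M)) < 1e-10) next
    x <- tryCatch(solve(M, b[combo]), error = function(e) NULL)
    if (is.null(x) || !feasible(x)) next
    val <- sum(obj * x)
    if (is.null(best) || (maximize && val > best) ||
        (!maximize && val < best)) best <- val
  }
  best # NULL = infeasible
}

# --- independent hypergeometric oracle: full enumeration -----------------
# P(X >= k) by enumerating every n-subset of an N-universe with K marks.
hyper_enum_oracle <- function(k, K, n, N) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  hits <- 0L; total <- 0L
  for (subset in utils::combn(N, n, simplify = FALSE)) {
    total <- total + 1L
    if (sum(subset %in% marked) >= k) hits <- hits + 1L
  }
  hits / total
}

# --- independent MTA scoring oracle --------------------------------------
# Exhaustive enumeration of achieved-change assignments, each checked by a
# bound-tightened minimum-deviation LP; mirrors the two-stage semantics
# without the MILP machinery.
mta_enum_oracle <- function(model, spec, ko, epsilon = 1) {
  rx <- model$reactions
  n <- nrow(rx)
  rid <- rx$id
  S <- stoichiometric_matrix(model)
  src <- spec$source_flux
  lo <- rx$lb; hi <- rx$ub
  if (!identical(ko, "wildtype")) {
    i <- match(ko, rid); lo[i] <- 0; hi[i] <- 0
  }
  # deviation LP: min sum |v - src| with given flux bounds
  min_dev <- function(lo2, hi2) {
    nv <- 2L * n
    mat <- cbind(S, matrix(0, nrow(S), nv))
    for (i in seq_len(n)) {
      row <- rep(0, n + nv)
      row[i] <- 1; row[n + 2 * i - 1] <- -1; row[n + 2 * i] <- 1
      mat <- rbind(mat, row)
    }
    obj <- c(rep(0, n), rep(1, nv))
    res <- solve_lp(obj, mat, c(rep("==", nrow(S)), rep("==", n)),
                    c(rep(0, nrow(S)), unname(src[rid])),
                    c(lo2, rep(0, nv)), c(hi2, rep(Inf, nv)))
    if (!identical(res$status, "optimal")) return(NULL)
    list(dev = res$objval,
         steady = sum(vapply(match(spec$R_S, rid), function(i)
           res$x[n + 2 * i - 1] + res$x[n + 2 * i], 0)))
  }
  base <- min_dev(lo, hi)
  dstar <- base$dev
  cues <- c(spec$R_F, spec$R_B)
  is_f <- cues %in% spec$R_F
  opts <- lapply(seq_along(cues), function(kk) {
    i <- match(cues[kk], rid)
    if (is_f[kk]) {
      t <- abs(src[[cues[kk]]]) + epsilon
      o <- list()
      if (hi[i] >= t) o <- c(o, list(c(i, t)))      # forward
      if (lo[i] <= -t) o <- c(o, list(c(i, -t)))    # backward
      o
    } else {
      t <- max(abs(src[[cues[kk]]]) - epsilon, 0)
      list(c(i, NA, t))                              # |v| <= t
    }
  })
  best_ach <- 0L; best_steady <- base$steady
  for (size in rev(seq_along(cues))) {
    if (size < best_ach) break
    for (idx in utils::combn(length(cues), size, simplify = FALSE)) {
      grid <- expand.grid(lapply(idx, function(kk)
        seq_along(opts[[kk]])))
      if (any(vapply(idx, function(kk) length(opts[[kk]]) == 0L, TRUE)))
        next
      for (g in seq_len(max(nrow(grid), 0))) {
        lo2 <- lo; hi2 <- hi; ok <- TRUE
        for (z in seq_along(idx)) {
          ch <- opts[[idx[z]]][[grid[g, z]]]
          i <- ch[1]
          if (length(ch) == 2L) {
            if (ch[2] > 0) lo2[i] <- max(lo2[i], ch[2])
            else hi2[i] <- min(hi2[i], ch[2])
          } else {
            lo2[i] <- max(lo2[i], -ch[3]); hi2[i] <- min(hi2[i], ch[3])
          }
          if (lo2[i] > hi2[i]) { ok <- FALSE; break }
        }
        if (!ok) next
        r <- min_dev(lo2, hi2)
        if (!is.null(r) && r$dev <= dstar + 1e-6 * (1 + dstar) &&
            size > best_ach) {
          best_ach <- size; best_steady <- r$steady
        }
      }
    }
    if (best_ach == size) break
  }
  mean_steady <- if (length(spec$R_S)) best_steady / length(spec$R_S) else 0
  list(achieved = best_ach, total_deviation = dstar,
       score = best_ach / (1 + mean_steady))
}

# random cued iMAT problem over a generated toy model
random_cue_problem <- function(seed, max_cues = 8, epsilon = 1) {
  model <- generate_toy_model(n_pathways = 2, reactions_per_pathway = 3,
                              gpr_complexity = 0.3, seed = seed)
  rids <- model$reactions$id
  set.seed(seed + 5000)
  ncue <- sample(2:max_cues, 1)
  cued <- sample(rids, min(ncue, length(rids)))
  lv <- sample(c(-1, 1), length(cued), replace = TRUE)
  imat_problem(model, R_H = cued[lv == 1], R_L = cued[lv == -1],
               epsilon = epsilon)
}
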