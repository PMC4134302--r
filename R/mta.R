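#' Build a transformation specification
#'
#' Partitions the reaction set into reactions required to increase
#' activity (`R_F`), required to decrease (`R_B`), and steady reactions
#' (`R_S`, everything else), together with the source-state flux the
#' transformation starts from.
#'
#' @param model a `metabolic_model`.
#' @param source_flux named flux vector over all reactions (typically
#'   from [solve_imat()] on the source condition).
#' @param R_F,R_B character vectors of reaction ids; must be disjoint.
#' @return object of class `transformation_spec`.
#' @export
transformation_spec <- function(model, source_flux, R_F = character(),
                                R_B = character()) {
  rids <- model$reactions$id
  stopifnot(all(c(R_F, R_B) %in% rids),
            !length(intersect(R_F, R_B)),
            all(rids %in% names(source_flux)))
  structure(list(source_flux = source_flux[rids],
                 R_F = unique(R_F), R_B = unique(R_B),
                 R_S = setdiff(rids, c(R_F, R_B))),
            class = "transformation_spec")
}

#' Derive changed/steady reaction sets from two expression states
#'
#' Per-gene two-sample rank-sum tests between source and target samples
#' with Benjamini-Hochberg control select significantly changed genes;
#' the per-gene change indicators (+1 up in target, -1 down) are pushed
#' through the GPRs (`and` = min, `or` = max) to label reactions. With
#' fewer than 2 samples per arm a fold-change rule is used instead.
#'
#' @param source_mat,target_mat genes x samples matrices for the source
#'   (e.g. disease) and target (e.g. healthy) states.
#' @param model a `metabolic_model`.
#' @param alpha FDR level (default 0.05).
#' @param method `"ranksum"` (default) or `"foldchange"`.
#' @param fc_threshold fold-change threshold on the (log-scale) mean
#'   difference for the fallback rule.
#' @param source_flux optional named flux vector to store in the spec;
#'   when `NULL` the spec's `source_flux` must be set before scoring.
#' @return a `transformation_spec` (with `gene_changes` attribute) when
#'   `source_flux` is given, otherwise a list with `R_F`, `R_B`, `R_S`,
#'   `gene_changes`.
#' @export
derive_change_sets <- function(source_mat, target_mat, model, alpha = 0.05,
                               method = c("ranksum", "foldchange"),
                               fc_threshold = 2, source_flux = NULL) {
  method <- match.arg(method)
  genes <- intersect(intersect(rownames(source_mat), rownames(target_mat)),
                     model$genes)
  if (!length(genes)) stop("no shared model genes between the two states")
  if (ncol(source_mat) == 0L || ncol(target_mat) == 0L)
    stop("empty condition matrix")
  if (method == "ranksum" && (ncol(source_mat) < 2L || ncol(target_mat) < 2L))
    method <- "foldchange"

  change <- stats::setNames(integer(length(genes)), genes)
  if (method == "ranksum") {
    pv <- vapply(genes, function(g)
      suppressWarnings(stats::wilcox.test(source_mat[g, ],
                                          target_mat[g, ])$p.value), 0)
    pv[is.na(pv)] <- 1
    qv <- bh_adjust(pv)
    sig <- qv <= alpha
    dirn <- sign(vapply(genes, function(g)
      stats::median(target_mat[g, ]) - stats::median(source_mat[g, ]), 0))
    change[sig] <- as.integer(dirn[sig])
  } else {
    diff <- rowMeans(target_mat[genes, , drop = FALSE]) -
      rowMeans(source_mat[genes, , drop = FALSE])
    change[diff >= log2(fc_threshold)] <- 1L
    change[diff <= -log2(fc_threshold)] <- -1L
  }

  rlev <- vapply(model$reactions$id, function(rid)
    eval_gpr(model$gpr_trees[[rid]], change), 0L)
  R_F <- model$reactions$id[rlev == 1L]
  R_B <- model$reactions$id[rlev == -1L]
  if (is.null(source_flux)) {
    list(R_F = R_F, R_B = R_B,
         R_S = setdiff(model$reactions$id, c(R_F, R_B)),
         gene_changes = change)
  } else {
    spec <- transformation_spec(model, source_flux, R_F, R_B)
    attr(spec, "gene_changes") <- change
    spec
  }
}

# Assemble the MTA MILP: flux variables, activity-change binaries for
# R_F (increase of |v| by >= epsilon over the source magnitude) and R_B
# (decrease to |v| <= max(|source| - epsilon, 0)), and split deviation
# variables |v - v_src| for every reaction. Direction binaries that the
# reaction's own bounds rule out are omitted.
build_mta_milp <- function(model, spec, ko_reactions, epsilon) {
  rx <- model$reactions
  n <- nrow(rx)
  rid <- rx$id
  S <- stoichiometric_matrix(model)
  lo <- rx$lb; hi <- rx$ub
  koi <- match(ko_reactions, rid)
  lo[koi] <- 0; hi[koi] <- 0
  src <- spec$source_flux

  obj1 <- rep(0, n)
  rows <- list(); dirs <- character(); rhs <- numeric()
  add_row <- function(coef, dir, b) {
    rows[[length(rows) + 1L]] <<- coef
    dirs[length(dirs) + 1L] <<- dir
    rhs[length(rhs) + 1L] <<- b
  }
  nv <- n
  for (r in spec$R_F) {
    i <- match(r, rid)
    t <- abs(src[[r]]) + epsilon
    cols <- integer()
    if (hi[i] >= t) {
      nv <- nv + 1L; obj1 <- c(obj1, 1); cols <- c(cols, nv)
      add_row(c(stats::setNames(1, i), stats::setNames(lo[i] - t, nv)),
              ">=", lo[i])
    }
    if (lo[i] <= -t) {
      nv <- nv + 1L; obj1 <- c(obj1, 1); cols <- c(cols, nv)
      add_row(c(stats::setNames(1, i), stats::setNames(hi[i] + t, nv)),
              "<=", hi[i])
    }
    if (length(cols) == 2L) add_row(stats::setNames(c(1, 1), cols), "<=", 1)
  }
  for (r in spec$R_B) {
    i <- match(r, rid)
    t <- max(abs(src[[r]]) - epsilon, 0)
    nv <- nv + 1L; obj1 <- c(obj1, 1)
    if (hi[i] > t)
      add_row(c(stats::setNames(1, i), stats::setNames(hi[i] - t, nv)),
              "<=", hi[i])
    if (lo[i] < -t)
      add_row(c(stats::setNames(1, i), stats::setNames(lo[i] + t, nv)),
              ">=", lo[i])
  }
  nbin <- nv - n
  # deviation splits for every reaction: v_i - d+ + d- = src_i
  dev_cols <- stats::setNames(vector("list", n), rid)
  for (i in seq_len(n)) {
    add_row(c(stats::setNames(1, i), stats::setNames(-1, nv + 1L),
              stats::setNames(1, nv + 2L)), "==", src[[rid[i]]])
    dev_cols[[i]] <- c(nv + 1L, nv + 2L)
    nv <- nv + 2L
  }
  lower <- c(lo, rep(0, nv - n))
  upper <- c(hi, rep(1, nbin), rep(Inf, 2L * n))
  obj1 <- c(obj1, rep(0, 2L * n))

  mat <- matrix(0, nrow = nrow(S) + length(rows), ncol = nv)
  mat[seq_len(nrow(S)), seq_len(n)] <- S
  for (k in seq_along(rows)) {
    coef <- rows[[k]]
    mat[nrow(S) + k, as.integer(names(coef))] <- coef
  }
  list(obj1 = obj1, mat = mat,
       dir = c(rep("==", nrow(S)), dirs),
       rhs = c(rep(0, nrow(S)), rhs),
       lower = lower, upper = upper,
       int_vars = seq.int(n + 1L, length.out = nbin),
       dev_cols = dev_cols, n = n)
}

#' Score a single knockout for source-to-target transformation
#'
#' The metabolic state after a knockout is predicted by minimal
#' adjustment: stage 1 finds the feasible steady-state flux closest to
#' the source state (minimum total `|v - v_source|`, a linear program,
#' with the knocked-out reaction fixed to zero). Stage 2 counts, among
#' the minimum-adjustment states, the largest number of desired changes
#' realized: R_F reactions increasing their absolute flux by at least
#' `epsilon` over the source magnitude, R_B reactions decreasing to at
#' most `max(|source| - epsilon, 0)`. A knockout unrelated to the
#' desired changes leaves the source state reachable and so achieves
#' nothing; only knockouts whose forced rerouting matches the target
#' direction score. The combined score is
#' `achieved / (1 + mean steady deviation)`, the steady deviation taken
#' over R_S at the stage-2 state.
#'
#' @param model a `metabolic_model`.
#' @param spec a `transformation_spec` with `source_flux` set.
#' @param ko reaction id to knock out, or `"wildtype"` for the
#'   no-knockout baseline, or a character vector of reactions to silence
#'   jointly (gene-level mode).
#' @param epsilon movement threshold (defaults to the iMAT activation
#'   threshold, 1).
#' @return list with `perturbation`, `achieved`, `steady_deviation`
#'   (mean over R_S), `total_deviation`, `score`, `status`.
#' @export
score_knockout <- function(model, spec, ko, epsilon = 1) {
  stopifnot(inherits(spec, "transformation_spec"))
  ko_rxns <- if (length(ko) == 1L && identical(ko, "wildtype")) character()
    else ko
  if (length(setdiff(ko_rxns, model$reactions$id)))
    stop("unknown knockout reaction: ",
         paste(setdiff(ko_rxns, model$reactions$id), collapse = ", "))
  p <- build_mta_milp(model, spec, ko_rxns, epsilon)
  label <- if (!length(ko_rxns)) "wildtype" else paste(ko, collapse = "+")
  devs <- unlist(p$dev_cols, use.names = FALSE)

  # stage 1: minimal adjustment (LP; activity binaries left relaxed and
  # unconstrained, so the cue rows cannot bind)
  obj_dev <- rep(0, ncol(p$mat)); obj_dev[devs] <- 1
  s1 <- solve_milp(obj_dev, p$mat, p$dir, p$rhs, p$lower, p$upper,
                   int_vars = integer(), maximize = FALSE)
  if (!identical(s1$status, "optimal"))
    stop("MTA adjustment LP not optimal for '", label, "' (", s1$status, ")")
  dstar <- max(s1$objval, 0)

  # stage 2: most target-consistent state among minimal-adjustment states
  achieved <- 0L
  x <- s1$x
  if (length(p$int_vars)) {
    lockrow <- obj_dev
    s2 <- solve_milp(p$obj1, rbind(p$mat, lockrow), c(p$dir, "<="),
                     c(p$rhs, dstar + 1e-6 * (1 + dstar)),
                     p$lower, p$upper, int_vars = p$int_vars,
                     maximize = TRUE, obj_integral = TRUE)
    if (!identical(s2$status, "optimal"))
      stop("MTA stage-2 MILP not optimal for '", label, "' (",
           s2$status, ")")
    achieved <- as.integer(round(s2$objval))
    x <- s2$x
  }
  steady_dev <- if (length(spec$R_S))
    sum(x[unlist(p$dev_cols[spec$R_S], use.names = FALSE)]) /
      length(spec$R_S) else 0
  # scrub solver-tolerance residue left by the deviation-lock slack
  if (steady_dev < 1e-5 * (1 + dstar)) steady_dev <- 0
  if (dstar < 1e-9) dstar <- 0
  list(perturbation = label, achieved = achieved,
       steady_deviation = steady_dev, total_deviation = dstar,
       score = achieved / (1 + steady_dev), status = "optimal")
}

#' Rank all knockouts by transformation score
#'
#' Scores every reaction knockout (or every gene knockout in gene-level
#' mode, silencing the reactions whose GPR evaluates false) plus the
#' wildtype baseline, and ranks them by descending score; ties are broken
#' by smaller steady deviation, then lexicographic id. Per-knockout
#' failures are reported as `NA` rows with a warning.
#'
#' @inheritParams score_knockout
#' @param level `"reaction"` (default) or `"gene"`.
#' @return data.frame with columns `perturbation`, `achieved`,
#'   `steady_deviation`, `score`, `rank`, `percentile` (100 = best).
#' @export
rank_perturbations <- function(model, spec, epsilon = 1,
                               level = c("reaction", "gene")) {
  level <- match.arg(level)
  perts <- if (level == "reaction") {
    stats::setNames(as.list(model$reactions$id), model$reactions$id)
  } else {
    stats::setNames(lapply(model$genes, function(g)
      reactions_silenced_by(model, g)), model$genes)
  }
  perts <- c(perts, list(wildtype = "wildtype"))
  rows <- lapply(names(perts), function(nm) {
    sc <- tryCatch(score_knockout(model, spec, perts[[nm]], epsilon),
                   error = function(e) {
                     warning("scoring failed for '", nm, "': ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(sc))
      return(data.frame(perturbation = nm, achieved = NA_integer_,
                        steady_deviation = NA_real_, score = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(perturbation = nm, achieved = sc$achieved,
               steady_deviation = sc$steady_deviation, score = sc$score,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$score, df$steady_deviation, df$perturbation,
               na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- seq_len(nrow(df))
  N <- nrow(df)
  df$percentile <- if (N > 1) 100 * (N - df$rank) / (N - 1) else 100
  df
}

#' Pathways enriched among top-scoring knockouts
#'
#' Takes the top fraction (default 10%) of ranked reaction knockouts
#' (wildtype excluded) and tests each pathway for enrichment against all
#' scored reactions.
#'
#' @param ranked data.frame from [rank_perturbations()] at reaction
#'   level.
#' @param model a `metabolic_model`.
#' @param top_fraction fraction of reactions taken as the target set
#'   (default 0.1).
#' @param alpha FDR level.
#' @return data.frame from [enrich_pathways()].
#' @export
mta_target_pathways <- function(ranked, model, top_fraction = 0.1,
                                alpha = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  scored <- ranked[ranked$perturbation != "wildtype" & !is.na(ranked$score), ]
  m <- ceiling(top_fraction * nrow(scored))
  top <- scored$perturbation[seq_len(m)]
  enrich_pathways(top, model, universe = scored$perturbation, alpha = alpha)
}
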