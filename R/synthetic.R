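# Seed-scoped RNG: evaluate code under a seed, then restore global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy metabolic model
#'
#' Builds linear pathways, each running from an uptake exchange through
#' labeled interior reactions to a secretion exchange, with optional
#' cross-links (shared metabolites) between adjacent pathways so that
#' perturbations have network-wide consequences. Interior reactions carry
#' one-to-one GPRs by default, with two-gene and/or composites at rate
#' `gpr_complexity`. Every reaction in the returned model is
#' flux-consistent (verified by unlocked FVA).
#'
#' @param n_pathways number of pathways.
#' @param reactions_per_pathway interior reactions per pathway.
#' @param n_exchanges_per_pathway exchange pairs per pathway; the first
#'   pair frames the pathway, extras attach to random interior
#'   metabolites.
#' @param reversible_fraction probability an interior reaction is
#'   reversible.
#' @param gpr_complexity probability an interior reaction gets a two-gene
#'   composite GPR instead of a single gene.
#' @param seed RNG seed; the same seed always yields the same model.
#' @param cross_links add one cross-link between each adjacent pathway
#'   pair (default TRUE).
#' @return a `metabolic_model` with an extra `gene_pathway` element
#'   (named character: gene id -> pathway label).
#' @export
generate_toy_model <- function(n_pathways = 4, reactions_per_pathway = 4,
                               n_exchanges_per_pathway = 1,
                               reversible_fraction = 0,
                               gpr_complexity = 0, seed = 1,
                               cross_links = TRUE) {
  stopifnot(n_pathways >= 1, reactions_per_pathway >= 1,
            n_exchanges_per_pathway >= 1)
  with_seed(seed, {
    mets <- list(); rx <- list(); stoich <- list()
    gene_pathway <- character()
    add_met <- function(id) mets[[length(mets) + 1L]] <<-
      data.frame(id = id, name = id, compartment = "c",
                 stringsAsFactors = FALSE)
    add_rxn <- function(id, st, lb, ub, gpr = "", pathway = "",
                        exchange = FALSE) {
      rx[[length(rx) + 1L]] <<- data.frame(
        id = id, lb = lb, ub = ub, gpr = gpr, pathway = pathway,
        exchange = exchange, stringsAsFactors = FALSE)
      stoich[[id]] <<- st
    }
    make_gpr <- function(rid, pw) {
      if (stats::runif(1) < gpr_complexity) {
        op <- if (stats::runif(1) < 0.5) "and" else "or"
        gs <- paste0("g_", rid, c("a", "b"))
        gene_pathway[gs] <<- pw
        paste0("(", gs[1], " ", op, " ", gs[2], ")")
      } else {
        g <- paste0("g_", rid)
        gene_pathway[g] <<- pw
        g
      }
    }
    K <- reactions_per_pathway
    for (p in seq_len(n_pathways)) {
      pw <- paste0("P", p)
      for (i in 0:K) add_met(sprintf("m_%d_%d", p, i))
      add_rxn(sprintf("EX_in_P%d", p),
              stats::setNames(-1, sprintf("m_%d_0", p)),
              -1000, 1000, pathway = pw, exchange = TRUE)
      for (i in seq_len(K)) {
        rid <- sprintf("R_%d_%d", p, i)
        rev <- stats::runif(1) < reversible_fraction
        add_rxn(rid,
                stats::setNames(c(-1, 1),
                                c(sprintf("m_%d_%d", p, i - 1),
                                  sprintf("m_%d_%d", p, i))),
                if (rev) -1000 else 0, 1000,
                gpr = make_gpr(rid, pw), pathway = pw)
      }
      add_rxn(sprintf("EX_out_P%d", p),
              stats::setNames(-1, sprintf("m_%d_%d", p, K)),
              -1000, 1000, pathway = pw, exchange = TRUE)
      if (n_exchanges_per_pathway > 1 && K > 1) {
        extra <- sample(seq_len(K - 1), min(n_exchanges_per_pathway - 1, K - 1))
        for (i in extra)
          add_rxn(sprintf("EX_m_%d_%d", p, i),
                  stats::setNames(-1, sprintf("m_%d_%d", p, i)),
                  -1000, 1000, pathway = pw, exchange = TRUE)
      }
    }
    if (cross_links && n_pathways > 1 && K > 2) {
      for (p in seq_len(n_pathways - 1)) {
        # late exit, early entry: the cross-link spans as much of both
        # pathways as possible, so a reroute through it has few
        # flux-equivalent neighbouring knockouts
        i <- K - 1L
        j <- 1L
        rid <- sprintf("CL_%d_%d", p, p + 1)
        add_rxn(rid,
                stats::setNames(c(-1, 1),
                                c(sprintf("m_%d_%d", p, i),
                                  sprintf("m_%d_%d", p + 1, j))),
                0, 1000, gpr = make_gpr(rid, paste0("P", p)),
                pathway = paste0("P", p))
      }
    }
    model <- metabolic_model(do.call(rbind, mets), do.call(rbind, rx), stoich)
    model$gene_pathway <- gene_pathway
    iv <- fva(model, lock = FALSE)
    blocked <- iv$reaction[iv$min == 0 & iv$max == 0]
    if (length(blocked))
      stop("generated model has blocked reactions: ",
           paste(blocked, collapse = ", "))
    model
  })
}

#' Simulate a two-condition expression dataset over a toy model
#'
#' Per-sample gene expression is `baseline + pathway shift (+ per-gene
#' shift) + Normal(0, noise_sd)` on a log2-like scale; shifts are
#' condition-specific and recorded in the returned ground truth.
#'
#' @param model a toy model from [generate_toy_model()].
#' @param condition_spec list with optional `baseline` (default 8) and a
#'   `conditions` list mapping condition name to
#'   `list(pathway_shifts = c(P2 = -3, ...), gene_shifts = c(...))`.
#' @param n_samples samples per condition (default 50).
#' @param noise_sd per-sample noise SD (default 1).
#' @param seed RNG seed.
#' @return list with `expression` (genes x samples matrix), `conditions`
#'   (named character vector sample -> condition) and `truth` (list with
#'   `seed`, `baseline`, `noise_sd`, per-condition shifts and
#'   `decreased_pathways`).
#' @export
simulate_expression <- function(model, condition_spec = list(),
                                n_samples = 50, noise_sd = 1, seed = 1) {
  baseline <- if (is.null(condition_spec$baseline)) 8 else
    condition_spec$baseline
  conds <- condition_spec$conditions
  if (is.null(conds))
    conds <- list(control = list(), disease = list())
  genes <- model$genes
  gp <- model$gene_pathway[genes]
  with_seed(seed, {
    mats <- list(); cond_vec <- character()
    for (cn in names(conds)) {
      ps <- conds[[cn]]$pathway_shifts
      gs <- conds[[cn]]$gene_shifts
      mu <- rep(baseline, length(genes))
      if (!is.null(ps)) {
        hit <- !is.na(gp) & gp %in% names(ps)
        mu[hit] <- mu[hit] + ps[gp[hit]]
      }
      if (!is.null(gs)) {
        hit <- genes %in% names(gs)
        mu[hit] <- mu[hit] + gs[genes[hit]]
      }
      m <- matrix(stats::rnorm(length(genes) * n_samples, mean = mu,
                               sd = noise_sd),
                  nrow = length(genes))
      rownames(m) <- genes
      colnames(m) <- sprintf("%s_%02d", cn, seq_len(n_samples))
      mats[[cn]] <- m
      cond_vec <- c(cond_vec,
                    stats::setNames(rep(cn, n_samples), colnames(m)))
    }
    shifts <- lapply(conds, function(x)
      list(pathway_shifts = as.list(x$pathway_shifts),
           gene_shifts = as.list(x$gene_shifts)))
    decreased <- character()
    if (length(conds) >= 2L) {
      p1 <- conds[[1]]$pathway_shifts; p2 <- conds[[2]]$pathway_shifts
      all_pw <- union(names(p1), names(p2))
      v1 <- stats::setNames(rep(0, length(all_pw)), all_pw)
      v2 <- v1
      v1[names(p1)] <- p1; v2[names(p2)] <- p2
      decreased <- all_pw[v2 < v1]
    }
    list(expression = do.call(cbind, mats), conditions = cond_vec,
         truth = list(seed = seed, baseline = baseline,
                      noise_sd = noise_sd, shifts = shifts,
                      decreased_pathways = decreased))
  })
}

#' Build a biomarker benchmark dataset with implanted exchange changes
#'
#' A balanced implant: one pathway is switched on in control and off in
#' disease (`pathway_down`), a second is switched off in control and on
#' in disease (`pathway_up`); the remaining pathways are unshifted
#' decoys. The balance keeps the per-sample expression mixture -- and
#' hence the across-gene discretization thresholds -- comparable between
#' conditions, so decoy pathways keep their cues. Under the pipeline this
#' implants a collapse of the down-pathway's exchange fluxes in disease
#' and an activation of the up-pathway's, and the truth lists the
#' expected biomarker calls at each pathway's inlet (uptake) and outlet
#' (secretion).
#'
#' @param model a toy model from [generate_toy_model()].
#' @param pathway_down,pathway_up implanted pathway labels; picking
#'   non-adjacent pathways (no shared cross-link) keeps the implants
#'   independent.
#' @param shift expression shift magnitude in SD units (default 3).
#' @param n_samples,noise_sd,seed passed to [simulate_expression()].
#' @return as [simulate_expression()], with
#'   `truth$implanted_biomarkers` (data.frame metabolite/direction) and
#'   `truth$decoy_exchanges` added.
#' @export
make_biomarker_dataset <- function(model, pathway_down = "P1",
                                   pathway_up = "P3", shift = 3,
                                   n_samples = 50, noise_sd = 1, seed = 1) {
  stopifnot(pathway_down != pathway_up)
  spec <- list(conditions = list(
    control = list(pathway_shifts = stats::setNames(
      c(shift, -shift), c(pathway_down, pathway_up))),
    disease = list(pathway_shifts = stats::setNames(
      c(-shift, shift), c(pathway_down, pathway_up)))))
  ds <- simulate_expression(model, spec, n_samples, noise_sd, seed)
  rx <- model$reactions
  met_of <- function(r) names(model$stoich[[r]])
  ds$truth$implanted_biomarkers <- data.frame(
    metabolite = c(met_of(paste0("EX_in_", pathway_down)),
                   met_of(paste0("EX_out_", pathway_down)),
                   met_of(paste0("EX_in_", pathway_up)),
                   met_of(paste0("EX_out_", pathway_up))),
    direction = c("uptake_decrease", "secretion_decrease",
                  "uptake_increase", "secretion_increase"),
    stringsAsFactors = FALSE)
  decoy <- rx$id[rx$exchange &
                   !(rx$pathway %in% c(pathway_down, pathway_up))]
  ds$truth$decoy_exchanges <- vapply(decoy, met_of, "")
  ds
}

#' Interior reactions suitable for knockout implants
#'
#' A cross-link gives the network an escape route: knocking out the
#' backbone reaction immediately downstream of a cross-link's exit
#' metabolite forces flux through the cross-link, producing an
#' expression signature with both up- and down-shifted genes. This
#' helper lists those reactions for a generated toy model.
#'
#' @param model a toy model from [generate_toy_model()] with
#'   cross-links.
#' @return character vector of reaction ids.
#' @export
implant_candidates <- function(model) {
  rx <- model$reactions
  cls <- rx$id[grepl("^CL_", rx$id)]
  out <- character()
  for (cl in cls) {
    st <- model$stoich[[cl]]
    exit_met <- names(st)[st < 0]
    for (rid in rx$id[!rx$exchange & !grepl("^CL_", rx$id)]) {
      s <- model$stoich[[rid]]
      if (exit_met %in% names(s)[s < 0]) out <- c(out, rid)
    }
  }
  unique(out)
}

#' Implant a knockout to create an MTA source/target pair
#'
#' The source flux template is an iMAT state with the pathway backbones
#' cued active and the cross-links cued inactive; the target template
#' re-solves the same cues with the knocked-out reaction forced to zero
#' flux, so the network reroutes through a cross-link (expression up in
#' the target) while the dead backbone tail shuts down (expression
#' down), with the knockout's own genes set low. Gene expression for
#' each state is high for genes of flux-carrying reactions and low
#' otherwise, plus noise. The truth records the implanted reaction.
#'
#' @param model a toy model from [generate_toy_model()] with
#'   cross-links.
#' @param ko interior reaction id to implant; see
#'   [implant_candidates()] for knockouts with a rerouting signature.
#' @param n_samples samples per condition (default 10).
#' @param noise_sd noise SD (default 1).
#' @param seed RNG seed.
#' @param epsilon activity threshold used for the flux templates.
#' @param delta_expr expression offset between active and inactive genes
#'   in SD units (default 8: the offset must clear the within-sample
#'   discretization threshold, mean + 0.3 SD of the bimodal mixture,
#'   by a wide margin for the 2/3 consensus to lock the cues).
#' @return list with `source` and `target` expression matrices, and
#'   `truth` (implanted `ko`, per-state active reaction sets, seed).
#' @export
implant_knockout_pair <- function(model, ko, n_samples = 10, noise_sd = 1,
                                  seed = 1, epsilon = 1, delta_expr = 8) {
  rx <- model$reactions
  stopifnot(ko %in% rx$id)
  catalyzed <- rx$id[nzchar(rx$gpr)]
  backbone <- catalyzed[!grepl("^CL_", catalyzed)]
  links <- catalyzed[grepl("^CL_", catalyzed)]
  src_sol <- solve_imat(imat_problem(model, R_H = backbone, R_L = links,
                                     epsilon = epsilon))
  model_ko <- model
  i <- match(ko, rx$id)
  model_ko$reactions$lb[i] <- 0
  model_ko$reactions$ub[i] <- 0
  tgt_sol <- solve_imat(imat_problem(model_ko, R_H = setdiff(backbone, ko),
                                     R_L = setdiff(links, ko),
                                     epsilon = epsilon))
  if (!identical(tgt_sol$status, "optimal") ||
      !any(tgt_sol$active[setdiff(catalyzed, ko)]))
    stop("knockout of '", ko, "' leaves a dead model")

  genes <- model$genes
  gene_rxns <- lapply(genes, function(g)
    rx$id[vapply(rx$id, function(r) g %in% gpr_genes(model$gpr_trees[[r]]),
                 TRUE)])
  names(gene_rxns) <- genes
  gene_active <- function(sol, off = character()) {
    vapply(genes, function(g) {
      rs <- setdiff(gene_rxns[[g]], off)
      length(rs) > 0L && any(sol$active[rs])
    }, TRUE)
  }
  act_src <- gene_active(src_sol)
  act_tgt <- gene_active(tgt_sol, off = ko)
  ko_genes <- gpr_genes(model$gpr_trees[[ko]])
  act_tgt[ko_genes] <- FALSE

  baseline <- 8
  with_seed(seed, {
    simulate <- function(active, prefix) {
      mu <- baseline + ifelse(active, delta_expr, -delta_expr)
      m <- matrix(stats::rnorm(length(genes) * n_samples, mean = mu,
                               sd = noise_sd), nrow = length(genes))
      rownames(m) <- genes
      colnames(m) <- sprintf("%s_%02d", prefix, seq_len(n_samples))
      m
    }
    list(source = simulate(act_src, "source"),
         target = simulate(act_tgt, "target"),
         truth = list(ko = ko, seed = seed,
                      source_active = names(act_src)[act_src],
                      target_active = names(act_tgt)[act_tgt]))
  })
}

#' Fixed toy network with forced post-transcriptional regulation calls
#'
#' A small branched network whose cues force, at every optimum, one
#' lowly-cued reaction to carry flux (post-transcriptional up-regulation)
#' and one highly-cued reaction to stay silent (down-regulation): the low
#' cue sits on the only supply of a doubly-cued branch, and one high cue
#' produces a dead-end metabolite.
#'
#' @return list with `model` (a `metabolic_model`) and `states` (named
#'   reaction cue levels).
#' @export
fig_fixture <- function() {
  mets <- data.frame(id = c("S", "A", "B", "C", "D", "F", "G"),
                     name = c("S", "A", "B", "C", "D", "F", "G"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_S", "R1", "R2", "R3", "R4", "R5", "R6", "EX_C", "EX_F"),
    lb = c(-1000, 0, 0, 0, 0, 0, 0, -1000, -1000),
    ub = 1000,
    gpr = c("", "g1", "g2", "g3", "g4", "g5", "g6", "", ""),
    pathway = c("Transport", "Upper", "Branch1", "Branch2", "Branch1",
                "Branch1", "Branch2", "Transport", "Transport"),
    exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_S = c(S = -1),
    R1 = c(S = -1, A = 1),
    R2 = c(A = -1, B = 1),
    R3 = c(A = -1, C = 1),
    R4 = c(B = -1, D = 1),
    R5 = c(D = -1, F = 1),
    R6 = c(C = -1, G = 1),
    EX_C = c(C = -1),
    EX_F = c(F = -1))
  model <- metabolic_model(mets, rxns, stoich)
  states <- stats::setNames(c(0L, 1L, -1L, 1L, 1L, 1L, 1L, 0L, 0L),
                            rxns$id)
  list(model = model, states = states)
}
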