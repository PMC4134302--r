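#' Assemble a pipeline configuration
#'
#' Defaults reproduce the study's stated parameter set: discretization at
#' mean +/- 0.3 SD, 2/3-of-samples consensus, reaction bounds within
#' -1000..1000 (from the model file), activation threshold 1,
#' interval-significance fraction 0.9 ("at least 90% lower"), FDR 0.05
#' and MTA top fraction 0.1.
#'
#' @param model path to a model file, or a `metabolic_model`.
#' @param expression path to an expression TSV, or a matrix.
#' @param conditions path to a sample-condition TSV, or a named vector.
#' @param control,disease condition labels; default the first two labels
#'   in order of appearance.
#' @param k,consensus_fraction,epsilon,delta,alpha,top_fraction numeric
#'   stage parameters (see module functions).
#' @param run_mta run the knockout-ranking stage (default TRUE).
#' @param seed integer seed recorded in the manifest.
#' @param outdir output directory for report TSVs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(model, expression, conditions,
                            control = NULL, disease = NULL,
                            k = 0.3, consensus_fraction = 2 / 3,
                            epsilon = 1, delta = 0.9, alpha = 0.05,
                            top_fraction = 0.1, run_mta = TRUE,
                            seed = 1L, outdir = tempfile("contextflux_run_")) {
  stopifnot(k > 0, consensus_fraction > 0, consensus_fraction <= 1,
            epsilon > 0, delta >= 0, delta < 1, alpha > 0, alpha <= 1,
            top_fraction > 0, top_fraction <= 1)
  structure(list(model = model, expression = expression,
                 conditions = conditions, control = control,
                 disease = disease, k = k,
                 consensus_fraction = consensus_fraction,
                 epsilon = epsilon, delta = delta, alpha = alpha,
                 top_fraction = top_fraction, run_mta = run_mta,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Recognized keys match the arguments of [pipeline_config()]; relative
#' paths are resolved against the config file's directory.
#'
#' @param path config file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
    else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("model", "expression", "conditions", "outdir"))
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  do.call(pipeline_config, raw)
}

# stable config fingerprint (FNV-1a over the canonical JSON encoding)
config_hash <- function(config) {
  keep <- config[setdiff(names(config), "outdir")]
  keep <- lapply(keep, function(x) if (is.character(x) || is.numeric(x) ||
                                       is.logical(x)) x else NULL)
  txt <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 1000000007
  sprintf("%09d", h)
}

write_report <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.10g", df[[cn]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Discretizes expression per condition, solves iMAT, computes
#' optimality-locked FVA intervals, compares control vs disease intervals
#' to call altered reactions and exchange-metabolite biomarkers, runs
#' pathway enrichment on the altered set, and (optionally) ranks
#' knockouts for transforming the disease state back toward control.
#' Every stage's table is written as TSV under `config$outdir` with a
#' config-hash header comment, alongside a JSON manifest. Reruns with an
#' identical config and seed produce byte-identical report TSVs.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest <- list(package_version = as.character(utils::packageVersion("contextflux")),
                   config_hash = hash, seed = config$seed,
                   parameters = config[c("k", "consensus_fraction", "epsilon",
                                         "delta", "alpha", "top_fraction")],
                   stages = list(), warnings = character())
  warn <- function(msg) manifest$warnings <<- c(manifest$warnings, msg)
  stage_time <- function(name, t) manifest$stages[[name]] <<-
    round(proc.time()[["elapsed"]] - t, 3)

  model <- if (inherits(config$model, "metabolic_model")) config$model
    else load_model(config$model)
  expr <- if (is.matrix(config$expression)) config$expression
    else read_expression(config$expression)
  cond <- if (is.character(config$conditions)) {
    if (length(config$conditions) == 1L && file.exists(config$conditions))
      read_conditions(config$conditions) else config$conditions
  } else config$conditions
  labs <- unique(cond[colnames(expr)])
  control <- if (is.null(config$control)) labs[1] else config$control
  disease <- if (is.null(config$disease)) labs[2] else config$disease

  res <- list(model = model)
  per_cond <- list()
  for (cn in c(control, disease)) {
    t1 <- proc.time()[["elapsed"]]
    sub <- expr[, names(cond)[cond == cn], drop = FALSE]
    st <- reaction_states_from_expression(model, sub, k = config$k,
                                          fraction = config$consensus_fraction)
    write_report(data.frame(reaction = names(st$reaction_states),
                            level = unname(st$reaction_states)),
                 file.path(config$outdir,
                           paste0("reaction_states_", cn, ".tsv")), hash)
    prob <- imat_problem(model, st$cues$R_H, st$cues$R_L,
                         epsilon = config$epsilon)
    sol <- solve_imat(prob)
    if (!identical(sol$status, "optimal")) {
      warn(paste0("iMAT not optimal for condition ", cn))
      per_cond[[cn]] <- list(states = st, failed = TRUE)
      next
    }
    ptr <- detect_ptr(st$reaction_states, sol)
    write_report(data.frame(reaction = names(sol$flux),
                            flux = unname(sol$flux),
                            active = unname(sol$active),
                            cue = unname(st$reaction_states[names(sol$flux)]),
                            ptr = unname(ptr[names(sol$flux)])),
                 file.path(config$outdir,
                           paste0("imat_solution_", cn, ".tsv")), hash)
    iv <- fva(model, prob, lock = TRUE, solution = sol)
    write_report(iv, file.path(config$outdir,
                               paste0("fva_intervals_", cn, ".tsv")), hash)
    per_cond[[cn]] <- list(states = st, problem = prob, solution = sol,
                           ptr = ptr, intervals = iv)
    stage_time(paste0("condition_", cn), t1)
  }
  res$conditions <- per_cond

  ok <- !isTRUE(per_cond[[control]]$failed) &&
    !isTRUE(per_cond[[disease]]$failed)
  if (ok) {
    t1 <- proc.time()[["elapsed"]]
    alt <- altered_reactions(per_cond[[control]]$intervals,
                             per_cond[[disease]]$intervals,
                             delta = config$delta)
    write_report(alt, file.path(config$outdir, "altered_reactions.tsv"),
                 hash)
    bm <- call_biomarkers(per_cond[[control]]$intervals,
                          per_cond[[disease]]$intervals, model,
                          delta = config$delta)
    write_report(bm, file.path(config$outdir, "biomarkers.tsv"), hash)
    enr <- if (nrow(alt)) enrich_pathways(
      intersect(alt$reaction, model$reactions$id[nzchar(model$reactions$pathway)]),
      model, alpha = config$alpha)
      else data.frame(pathway = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical())
    write_report(enr, file.path(config$outdir, "enrichment_altered.tsv"),
                 hash)
    res$altered <- alt; res$biomarkers <- bm; res$enrichment <- enr
    stage_time("compare", t1)
  } else {
    warn("comparison stage skipped: an iMAT stage failed")
  }

  if (ok && isTRUE(config$run_mta)) {
    t1 <- proc.time()[["elapsed"]]
    src_mat <- expr[, names(cond)[cond == disease], drop = FALSE]
    tgt_mat <- expr[, names(cond)[cond == control], drop = FALSE]
    spec <- derive_change_sets(src_mat, tgt_mat, model,
                               alpha = config$alpha,
                               source_flux = per_cond[[disease]]$solution$flux)
    ranked <- rank_perturbations(model, spec, epsilon = config$epsilon)
    write_report(ranked, file.path(config$outdir, "mta_scores.tsv"), hash)
    tp <- mta_target_pathways(ranked, model,
                              top_fraction = config$top_fraction,
                              alpha = config$alpha)
    write_report(tp, file.path(config$outdir, "mta_target_pathways.tsv"),
                 hash)
    res$mta <- list(spec = spec, ranked = ranked, target_pathways = tp)
    stage_time("mta", t1)
  }

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Sweep the interval-significance (or discretization) threshold
#'
#' Re-runs the interval-comparison and enrichment stage for each value of
#' `delta` (or of `k`, re-discretizing), and reports per-pathway
#' enrichment across values together with the robust intersection of
#' altered reactions.
#'
#' @param config a `pipeline_config`.
#' @param delta_values,k_values numeric vectors; supply exactly one.
#' @return list with `enrichment` (pathway x value flag table),
#'   `altered` (per-value altered sets) and `robust` (reactions altered
#'   at every value).
#' @export
threshold_sweep <- function(config, delta_values = NULL, k_values = NULL) {
  if (is.null(delta_values) == is.null(k_values))
    stop("supply exactly one of delta_values or k_values")
  values <- if (!is.null(delta_values)) delta_values else k_values
  if (length(values) < 2L) stop("need at least 2 threshold values")
  labels <- make.unique(as.character(values))
  runs <- list()
  for (i in seq_along(values)) {
    cfg <- config
    if (!is.null(delta_values)) cfg$delta <- values[i] else
      cfg$k <- values[i]
    cfg$run_mta <- FALSE
    cfg$outdir <- file.path(config$outdir, paste0("sweep_", labels[i]))
    runs[[labels[i]]] <- run_pipeline(cfg)
  }
  alt_sets <- lapply(runs, function(r) r$altered$reaction)
  pw <- sort(unique(unlist(lapply(runs, function(r) r$enrichment$pathway))))
  enr <- data.frame(pathway = pw, stringsAsFactors = FALSE)
  for (v in names(runs)) {
    e <- runs[[v]]$enrichment
    enr[[paste0("enriched_", v)]] <- pw %in% e$pathway[e$enriched]
  }
  list(enrichment = enr, altered = alt_sets,
       robust = Reduce(intersect, alt_sets))
}
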