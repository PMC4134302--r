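#' Construct a metabolic model
#'
#' A `metabolic_model` bundles metabolites, reactions (with bounds,
#' gene-protein-reaction rules, pathway labels and exchange flags) and the
#' per-reaction stoichiometry. Exchange reactions are written as
#' `met <-> (outside)` with coefficient -1, so positive flux is secretion
#' (export) and negative flux is uptake; this sign convention is relied on
#' throughout, in particular when biomarker directions are called.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `gpr`
#'   (infix rule string, possibly empty), `pathway` (possibly empty),
#'   `exchange` (logical).
#' @param stoich named list (by reaction id) of named numeric vectors
#'   (metabolite id -> signed coefficient, negative = consumed).
#' @return validated object of class `metabolic_model` with a `genes`
#'   element holding the union of GPR leaves.
#' @export
metabolic_model <- function(metabolites, reactions, stoich) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("id", "name", "compartment"))
    if (is.null(metabolites[[col]])) stop("metabolites need column '", col, "'")
  for (col in c("id", "lb", "ub"))
    if (is.null(reactions[[col]])) stop("reactions need column '", col, "'")
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$pathway)) reactions$pathway <- ""
  if (is.null(reactions$exchange)) reactions$exchange <- FALSE
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$pathway[is.na(reactions$pathway)] <- ""
  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      stoich = stoich, genes = character()),
                 class = "metabolic_model")
  m$gpr_trees <- lapply(reactions$gpr, parse_gpr)
  names(m$gpr_trees) <- reactions$id
  m$genes <- sort(unique(unlist(lapply(m$gpr_trees, gpr_genes))))
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, bound ordering, stoichiometry references and the
#' single-metabolite form of exchange reactions. Called by every
#' constructor/reader; exposed for use after manual edits.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending record.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (any(!nzchar(mets$compartment)))
    stop("metabolite with empty compartment: ",
         paste(mets$id[!nzchar(mets$compartment)], collapse = ", "))
  bad <- rxns$lb > rxns$ub
  if (any(bad))
    stop("lower bound exceeds upper bound for reaction: ",
         paste(rxns$id[bad], collapse = ", "))
  if (!setequal(names(model$stoich), rxns$id))
    stop("stoichiometry entries do not match reaction ids")
  for (rid in rxns$id) {
    st <- model$stoich[[rid]]
    if (length(st) == 0L) stop("reaction '", rid, "' has empty stoichiometry")
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction '", rid, "' references undefined metabolite: ",
           paste(unknown, collapse = ", "))
  }
  ex <- rxns$id[rxns$exchange]
  for (rid in ex)
    if (length(model$stoich[[rid]]) != 1L)
      stop("exchange reaction '", rid, "' must touch exactly one metabolite")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes,",
      sum(x$reactions$exchange), "exchange reactions\n")
  pw <- setdiff(unique(x$reactions$pathway), "")
  if (length(pw)) cat("pathways:", paste(pw, collapse = ", "), "\n")
  invisible(x)
}

#' Read a metabolic model from file
#'
#' Reads the canonical JSON dialect (see `write_model`) or an SBML Level 3
#' subset (species, reaction stoichiometry, bounds via fbc attributes or
#' reversibility, GPR and pathway from COBRA-style notes).
#' Reactions without bounds in the file receive the default bounds
#' \[-1000, 1000\].
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension when
#'   missing.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed model JSON in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("model JSON must contain 'metabolites' and 'reactions' arrays")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), ""),
    name = vapply(doc$metabolites, function(m)
      as.character(if (is.null(m$name)) m$id else m$name), ""),
    compartment = vapply(doc$metabolites, function(m)
      as.character(if (is.null(m$compartment)) "c" else m$compartment), ""),
    stringsAsFactors = FALSE)
  getf <- function(r, f, default) if (is.null(r[[f]])) default else r[[f]]
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) {
      if (is.null(r$id)) stop("reaction record without id in '", path, "'")
      as.character(r$id)
    }, ""),
    lb = vapply(doc$reactions, function(r) as.numeric(getf(r, "lb", -1000)), 0),
    ub = vapply(doc$reactions, function(r) as.numeric(getf(r, "ub", 1000)), 0),
    gpr = vapply(doc$reactions, function(r) as.character(getf(r, "gpr", "")), ""),
    pathway = vapply(doc$reactions, function(r)
      as.character(getf(r, "pathway", "")), ""),
    exchange = vapply(doc$reactions, function(r)
      isTRUE(getf(r, "exchange", FALSE)), TRUE),
    stringsAsFactors = FALSE)
  stoich <- lapply(doc$reactions, function(r) {
    if (is.null(r$mets) || !length(r$mets))
      stop("reaction '", r$id, "' has no stoichiometry")
    unlist(r$mets)
  })
  names(stoich) <- rxns$id
  metabolic_model(mets, rxns, stoich)
}

#' Write a metabolic model to the canonical JSON dialect
#'
#' The dialect: `{"metabolites": [{"id","name","compartment"}, ...],
#' "reactions": [{"id", "mets": {met: coeff}, "lb", "ub", "gpr",
#' "pathway", "exchange"}, ...]}`. `load_model(write_model(m))` restores
#' the model field by field.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rx <- model$reactions
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      as.list(model$metabolites[i, c("id", "name", "compartment")])),
    reactions = lapply(seq_len(nrow(rx)), function(i) {
      st <- model$stoich[[rx$id[i]]]
      list(id = rx$id[i], mets = as.list(st), lb = rx$lb[i], ub = rx$ub[i],
           gpr = rx$gpr[i], pathway = rx$pathway[i],
           exchange = rx$exchange[i])
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns_strip <- xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(species, "compartment")), "c",
                         xml2::xml_attr(species, "compartment")),
    stringsAsFactors = FALSE)[!boundary, , drop = FALSE]
  boundary_ids <- xml2::xml_attr(species, "id")[boundary]

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- as.numeric(xml2::xml_attr(params, "value"))
  names(pval) <- xml2::xml_attr(params, "id")

  note_field <- function(node, key) {
    txt <- xml2::xml_text(xml2::xml_find_all(node, ".//notes//p"))
    hit <- grep(paste0("^\\s*", key, "\\s*:"), txt, value = TRUE)
    if (!length(hit)) return("")
    trimws(sub(paste0("^\\s*", key, "\\s*:"), "", hit[1]))
  }

  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ids <- xml2::xml_attr(rnodes, "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction id in SBML: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stoich <- list(); lb <- ub <- numeric(length(rnodes))
  gpr <- pathway <- character(length(rnodes))
  for (i in seq_along(rnodes)) {
    node <- rnodes[[i]]
    rev <- !identical(xml2::xml_attr(node, "reversible"), "false")
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    lb[i] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    reac <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    coef <- function(nodes, sign) {
      s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      s[is.na(s)] <- 1
      stats::setNames(sign * s, xml2::xml_attr(nodes, "species"))
    }
    st <- c(coef(reac, -1), coef(prod, 1))
    st <- st[!(names(st) %in% boundary_ids)]
    if (!length(st)) stop("reaction '", ids[i],
                          "' has no internal-species stoichiometry")
    stoich[[ids[i]]] <- st
    gpr[i] <- note_field(node, "GENE_ASSOCIATION")
    pathway[i] <- note_field(node, "SUBSYSTEM")
  }
  exchange <- vapply(stoich, function(s) length(s) == 1L, TRUE) &
    (grepl("^EX_", ids) | vapply(seq_along(rnodes), function(i) {
      np <- length(xml2::xml_find_all(rnodes[[i]], "./listOfProducts/speciesReference"))
      nr <- length(xml2::xml_find_all(rnodes[[i]], "./listOfReactants/speciesReference"))
      n_bound <- sum(c(names(stoich[[ids[i]]])) %in% boundary_ids)
      (np + nr) > length(stoich[[ids[i]]]) || (np == 0L || nr == 0L)
    }, TRUE))
  rxns <- data.frame(id = ids, lb = lb, ub = ub, gpr = gpr,
                     pathway = pathway, exchange = unname(exchange),
                     stringsAsFactors = FALSE)
  metabolic_model(mets, rxns, stoich)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites (rows, declaration order) by
#'   reactions (columns, declaration order).
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (rid in rids) {
    st <- model$stoich[[rid]]
    S[names(st), rid] <- st
  }
  S
}

#' Genes of a model whose loss silences a reaction
#'
#' Evaluates each reaction's GPR with the given genes set to FALSE (absent)
#' and all others TRUE.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of knocked-out gene ids.
#' @return character vector of silenced reaction ids.
#' @export
reactions_silenced_by <- function(model, genes) {
  off <- vapply(model$reactions$id, function(rid) {
    g <- model$gpr_trees[[rid]]
    if (is.null(g)) return(FALSE)
    !eval_gpr_bool(g, genes)
  }, TRUE)
  model$reactions$id[off]
}

eval_gpr_bool <- function(tree, off_genes) {
  if (tree$kind == "leaf") return(!(tree$gene %in% off_genes))
  vals <- vapply(tree$children, eval_gpr_bool, TRUE, off_genes = off_genes)
  if (tree$kind == "and") all(vals) else any(vals)
}
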